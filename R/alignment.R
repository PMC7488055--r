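#' Nucleotide alignments
#'
#' A `dna_alignment` is a character matrix of IUPAC nucleotide symbols
#' (including gaps `-` and ambiguity codes) with unique taxon labels as rows.
#'
#' @param seqs Named list of equal-length character vectors, or a character
#'   matrix with rownames.
#' @param locus Optional locus label.
#' @return Object of class `dna_alignment`: list with `taxa`, `mat`
#'   (taxa x sites character matrix, upper case) and `locus`.
#' @export
dna_alignment <- function(seqs, locus = NA_character_) {
  if (is.matrix(seqs)) {
    mat <- seqs
    taxa <- rownames(mat)
  } else {
    taxa <- names(seqs)
    lens <- lengths(seqs)
    if (length(unique(lens)) > 1L) {
      off <- taxa[which(lens != lens[1L])[1L]]
      stop(sprintf("ragged alignment: taxon '%s' has %d sites, expected %d",
                   off, lens[lens != lens[1L]][1L], lens[1L]))
    }
    mat <- do.call(rbind, seqs)
    rownames(mat) <- taxa
  }
  if (is.null(taxa) || any(!nzchar(taxa))) stop("all sequences must be named")
  if (anyDuplicated(taxa)) {
    stop(sprintf("duplicate taxon label '%s'", taxa[duplicated(taxa)][1L]))
  }
  mat[] <- toupper(mat)
  structure(list(taxa = taxa, mat = mat, locus = locus), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment '%s': %d taxa, %d sites\n",
              x$locus, length(x$taxa), n_sites(x)))
  invisible(x)
}

#' Number of aligned columns
#' @param a A [dna_alignment()].
#' @export
n_sites <- function(a) ncol(a$mat)

#' Read a multiple sequence alignment
#'
#' FASTA and NEXUS (sequential and interleaved DATA blocks) are parsed with
#' ape; relaxed sequential PHYLIP (whitespace-separated names of any length,
#' sequences possibly wrapped) is parsed directly.
#'
#' @param path Input file.
#' @param format One of `"fasta"`, `"nexus"`, `"phylip-relaxed"`.
#' @param locus Locus label recorded in the alignment (defaults to the
#'   file name without extension).
#' @return A [dna_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "nexus", "phylip-relaxed"),
                           locus = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  seqs <- switch(format,
    fasta = {
      x <- as.character(ape::read.FASTA(path))
      lapply(x, function(s) toupper(unname(s)))
    },
    nexus = {
      x <- ape::read.nexus.data(path)
      lapply(x, toupper)
    },
    `phylip-relaxed` = read_phylip_relaxed(path)
  )
  dna_alignment(seqs, locus = locus)
}

read_phylip_relaxed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1L], what = numeric(), quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed PHYLIP header")
  ntax <- as.integer(hdr[1L]); nchar_ <- as.integer(hdr[2L])
  seqs <- list(); cur <- NULL
  for (ln in lines[-1L]) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (is.null(cur) || nchar(paste(seqs[[cur]], collapse = "")) >= nchar_) {
      cur <- toks[1L]
      seqs[[cur]] <- paste(toks[-1L], collapse = "")
    } else {
      seqs[[cur]] <- paste0(seqs[[cur]], paste(toks, collapse = ""))
    }
  }
  if (length(seqs) != ntax) {
    stop(sprintf("PHYLIP header promises %d taxa, found %d", ntax, length(seqs)))
  }
  lapply(seqs, function(s) {
    v <- strsplit(s, "")[[1L]]
    if (length(v) != nchar_) {
      stop(sprintf("ragged alignment: taxon has %d sites, expected %d",
                   length(v), nchar_))
    }
    v
  })
}

#' Write an alignment
#'
#' Writers are bit-stable given identical inputs.
#' @param a A [dna_alignment()].
#' @param path Output file.
#' @param format `"fasta"` or `"phylip-relaxed"`.
#' @export
write_alignment <- function(a, path, format = c("fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(a$taxa)) {
      writeLines(c(paste0(">", a$taxa[i]),
                   paste(a$mat[i, ], collapse = "")), con)
    }
  } else {
    writeLines(sprintf("%d %d", length(a$taxa), n_sites(a)), con)
    for (i in seq_along(a$taxa)) {
      writeLines(paste(a$taxa[i], paste(a$mat[i, ], collapse = "")), con)
    }
  }
  invisible(path)
}

#' Concatenate per-locus alignments
#'
#' Taxa missing from a locus are padded with gaps, matching the common
#' practice of retaining terminals that lack some loci.  The per-locus
#' column ranges are recorded as a partition map.
#'
#' @param alignments List of [dna_alignment()] objects.
#' @return A [dna_alignment()] over the union of taxa (order of first
#'   appearance), with attribute `partition`: a data.frame with columns
#'   `locus`, `start`, `end`.
#' @export
concatenate_alignments <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  stopifnot(all(vapply(alignments, inherits, logical(1), "dna_alignment")))
  taxa <- unique(unlist(lapply(alignments, `[[`, "taxa")))
  widths <- vapply(alignments, n_sites, integer(1))
  total <- sum(widths)
  mat <- matrix("-", nrow = length(taxa), ncol = total, dimnames = list(taxa, NULL))
  pos <- 0L
  part <- data.frame(locus = vapply(alignments, `[[`, character(1), "locus"),
                     start = integer(length(alignments)),
                     end = integer(length(alignments)))
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    mat[a$taxa, pos + seq_len(widths[k])] <- a$mat
    part$start[k] <- pos + 1L
    part$end[k] <- pos + widths[k]
    pos <- pos + widths[k]
  }
  out <- dna_alignment(mat, locus = "concatenated")
  attr(out, "partition") <- part
  out
}

#' Count parsimony-informative sites
#'
#' A column is parsimony informative when at least two distinct unambiguous
#' nucleotide states (A/C/G/T) are each present in at least two sequences.
#' Gaps and IUPAC ambiguity codes are not counted as states.
#'
#' @param a A [dna_alignment()].
#' @return Integer count of informative columns (0 for an empty alignment).
#' @export
count_parsimony_informative <- function(a) {
  if (n_sites(a) == 0L) return(0L)
  bases <- c("A", "C", "G", "T")
  m <- a$mat
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  sum(rowSums(counts >= 2) >= 2)
}

#' UPGMA clock tree from an alignment
#'
#' A distance-based stand-in for model-based clock gene-tree estimation:
#' pairwise p-distances over site pairs where both sequences carry an
#' unambiguous base, optionally Jukes-Cantor corrected
#' (d = -(3/4) log(1 - 4p/3)), then average-linkage (UPGMA) clustering.
#' The output is ultrametric by construction.
#'
#' @param a A [dna_alignment()] with at least 2 taxa.
#' @param correction `"raw"` (p-distance) or `"jc69"`.
#' @return A [clock_tree()].
#' @export
upgma_clock_tree <- function(a, correction = c("raw", "jc69")) {
  correction <- match.arg(correction)
  nt <- length(a$taxa)
  if (nt < 2L) stop("need at least 2 taxa")
  good <- a$mat %in% c("A", "C", "G", "T")
  dim(good) <- dim(a$mat)
  D <- matrix(0, nt, nt, dimnames = list(a$taxa, a$taxa))
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      ok <- good[i, ] & good[j, ]
      nok <- sum(ok)
      if (nok == 0L) stop(sprintf("no comparable sites between '%s' and '%s'",
                                  a$taxa[i], a$taxa[j]))
      p <- sum(a$mat[i, ok] != a$mat[j, ok]) / nok
      d <- if (correction == "jc69") {
        if (p >= 0.75) {
          stop(sprintf("JC69 distance undefined for pair '%s'/'%s' (p = %.3f >= 0.75)",
                       a$taxa[i], a$taxa[j], p))
        }
        -0.75 * log(1 - 4 * p / 3)
      } else p
      D[i, j] <- D[j, i] <- d
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)   # node heights = hclust heights / 2
  clock_tree(phy, tolerance = 1e-9)
}

#' Read taxon-map and trait TSV files
#'
#' The taxon map assigns each individual to exactly one candidate species;
#' the optional trait table holds categorical traits per individual.
#'
#' @param taxon_map_path TSV with header; first column individual labels,
#'   second column candidate-species labels.
#' @param trait_path Optional TSV with header; first column individual
#'   labels, remaining columns categorical traits.
#' @param trait_levels Optional named list of allowed levels per trait;
#'   values outside the declared set raise an error.
#' @return List with `taxon_map` (see [taxon_map()]) and `traits`
#'   (data.frame or NULL).  Missing trait values (empty or NA) are kept as NA.
#' @export
read_mappings <- function(taxon_map_path, trait_path = NULL, trait_levels = NULL) {
  tm <- utils::read.delim(taxon_map_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  map <- taxon_map(tm[[1L]], tm[[2L]])
  traits <- NULL
  if (!is.null(trait_path)) {
    tt <- utils::read.delim(trait_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, na.strings = c("NA", ""))
    if (anyDuplicated(tt[[1L]])) stop("duplicate individual in trait table")
    rownames(tt) <- tt[[1L]]
    traits <- tt[, -1L, drop = FALSE]
    if (!is.null(trait_levels)) {
      for (nm in names(trait_levels)) {
        if (!nm %in% names(traits)) next
        bad <- setdiff(stats::na.omit(unique(traits[[nm]])), trait_levels[[nm]])
        if (length(bad)) {
          stop(sprintf("unknown level '%s' for trait '%s'", bad[1L], nm))
        }
        traits[[nm]] <- factor(traits[[nm]], levels = trait_levels[[nm]])
      }
    }
  }
  list(taxon_map = map, traits = traits)
}

#' Individual-to-species assignment
#'
#' @param individual Character vector of individual labels.
#' @param species Character vector of candidate-species labels, same length.
#' @return Object of class `taxon_map`: a data.frame with columns
#'   `individual` and `species`.  An individual assigned to two different
#'   species is an error; exact duplicate rows are collapsed.
#' @export
taxon_map <- function(individual, species) {
  df <- unique(data.frame(individual = as.character(individual),
                          species = as.character(species),
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$individual)) {
    dup <- df$individual[duplicated(df$individual)][1L]
    stop(sprintf("individual '%s' assigned to more than one species", dup))
  }
  class(df) <- c("taxon_map", "data.frame")
  df
}

# species for a set of individual labels, with error on unmatched tips
map_species <- function(map, individuals) {
  i <- match(individuals, map$individual)
  if (anyNA(i)) {
    stop(sprintf("gene-tree tip '%s' not present in the taxon map",
                 individuals[which(is.na(i))[1L]]))
  }
  map$species[i]
}
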