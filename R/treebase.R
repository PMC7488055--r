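#' Fetch deposited alignment matrices from TreeBase
#'
#' Downloads the NEXUS matrices of a TreeBase study (default: the Rostania
#' multilocus study, TB2:S26825) into a local directory.  Requires network
#' access; everything else in the package works offline.
#'
#' @param dest_dir Directory to write the `.nex` files into.
#' @param study TreeBase study accession.
#' @param timeout Seconds allowed per request.
#' @return Character vector of downloaded file paths.
#' @export
fetch_treebase_matrices <- function(dest_dir, study = "TB2:S26825",
                                    timeout = 60) {
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  old <- getOption("timeout"); options(timeout = timeout)
  on.exit(options(timeout = old))
  base <- "http://purl.org/phylo/treebase/phylows"
  study_url <- sprintf("%s/study/%s?format=html", base, study)
  page <- paste(readLines(url(study_url), warn = FALSE), collapse = "\n")
  mids <- unique(regmatches(page, gregexpr("TB2:M[0-9]+", page))[[1L]])
  if (!length(mids)) stop("no matrices found in the TreeBase study page")
  vapply(mids, function(mid) {
    dest <- file.path(dest_dir, paste0(sub(":", "_", mid), ".nex"))
    utils::download.file(sprintf("%s/matrix/%s?format=nexus", base, mid),
                         dest, quiet = TRUE)
    dest
  }, character(1))
}

#' Summary statistics of a set of deposited matrices
#'
#' Reads NEXUS alignments, concatenates them with gap padding, and reports
#' per-locus and total widths, the number of terminals in the concatenated
#' matrix, and parsimony-informative site counts.
#'
#' @param paths NEXUS alignment files.
#' @return List with `per_locus` (data.frame: locus, width, pis),
#'   `total_width`, `n_terminals`, `total_pis`.
#' @export
matrix_stats <- function(paths) {
  alns <- lapply(paths, read_alignment, format = "nexus")
  conc <- concatenate_alignments(alns)
  per <- data.frame(
    locus = vapply(alns, `[[`, character(1), "locus"),
    width = vapply(alns, n_sites, integer(1)),
    pis = vapply(alns, function(a) as.integer(count_parsimony_informative(a)),
                 integer(1)))
  list(per_locus = per, total_width = n_sites(conc),
       n_terminals = length(conc$taxa),
       total_pis = count_parsimony_informative(conc))
}
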