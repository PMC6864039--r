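#' Reference tables from the 29-patient clinical cohort
#'
#' Summary numbers of the clinical study the method was developed on, bundled
#' as plain-text data: the voxel label counts behind the background
#' distributions (`"counts"`), and the optimized leave-one-out classification
#' results under Benjamini-Hochberg (`"bh"`) and random-field-theory
#' (`"rft"`) correction. The raw patient images are an external download and
#' are not redistributed here; these tables carry the published per-outcome
#' summaries the package's arithmetic can be checked against.
#'
#' @param which `"counts"`, `"bh"`, or `"rft"`.
#' @return data.frame. For `"counts"`: outcome, n_pos, n_neg (voxels). For
#'   `"bh"`/`"rft"`: outcome, k_opt, acc, n_sig, sens (percent); `NA` marks
#'   the outcome for which no voxel passed correction at any k.
#' @export
referenceCohortTable <- function(which = c("counts", "bh", "rft")) {
  which <- match.arg(which)
  file <- c(counts = "cohort_voxel_counts.tsv",
            bh = "cohort_results_bh.tsv",
            rft = "cohort_results_rft.tsv")[[which]]
  path <- system.file("extdata", file, package = "multiscaleMRI")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Mean and population standard deviation of cohort summaries
#'
#' The cohort-level accuracy/sensitivity summaries are the mean and the
#' population (divide-by-n) standard deviation over the outcomes that
#' produced significant voxels; `NA` entries are dropped.
#'
#' @param x Numeric vector of per-outcome values.
#' @return List with `mean` and `sd` (population SD).
#' @export
cohortSummaryStats <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)))
}
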