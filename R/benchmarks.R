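#' Published TCGA benchmark tables bundled with the package
#'
#' Mean +/- SD Ctd and IBS over 50 random splits for the four model
#' variants on the TCGA BLCA (bladder) and KIRC (kidney clear cell)
#' cohorts, as reported for this method, together with the cohorts'
#' censored/uncensored counts. These tables are reference inputs for
#' relative-improvement arithmetic; the package does not download TCGA
#' data.
#'
#' @param cohort `"blca"` or `"kirc"`.
#' @return Data frame with columns `model`, `survival_model`, `ctd_mean`,
#'   `ctd_sd`, `ibs_mean`, `ibs_sd`.
#' @export
benchmark_table <- function(cohort = c("blca", "kirc")) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata", sprintf("benchmark_%s.tsv", cohort),
                      package = "gnnsurv", mustWork = TRUE)
  utils::read.delim(path)
}

#' @rdname benchmark_table
#' @return `cohort_counts`: data frame with `cohort`, `n_censored`,
#'   `n_uncensored`.
#' @export
cohort_counts <- function() {
  path <- system.file("extdata", "cohort_counts.tsv", package = "gnnsurv",
                      mustWork = TRUE)
  utils::read.delim(path)
}

#' Relative improvement of a model over the MLP baseline
#'
#' Percentage gain in mean Ctd, `100 * (model - mlp) / mlp`, or percentage
#' reduction in mean IBS, `100 * (mlp - model) / mlp`, read off a benchmark
#' table.
#'
#' @param table A [benchmark_table()]-shaped data frame.
#' @param model One of `"gcn"`, `"sage"`, `"gat"`.
#' @param survival_model `"logistic_hazard"` or `"pmf"`.
#' @param metric `"ctd"` (gain) or `"ibs"` (reduction).
#' @return Percentage as a plain number.
#' @export
relative_improvement <- function(table, model,
                                 survival_model = c("logistic_hazard", "pmf"),
                                 metric = c("ctd", "ibs")) {
  survival_model <- match.arg(survival_model)
  metric <- match.arg(metric)
  col <- paste0(metric, "_mean")
  pick <- function(mod) {
    v <- table[table$model == mod & table$survival_model == survival_model,
               col]
    if (length(v) != 1L) stop("no unique row for model ", mod)
    v
  }
  ref <- pick("mlp")
  val <- pick(model)
  if (metric == "ctd") 100 * (val - ref) / ref else 100 * (ref - val) / ref
}

#' Censoring rate from censored/uncensored counts
#'
#' @param n_censored,n_uncensored Cohort counts.
#' @return Censoring rate in percent.
#' @export
censoring_rate <- function(n_censored, n_uncensored) {
  100 * n_censored / (n_censored + n_uncensored)
}
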