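#' Read a tab-separated expression matrix (genes x samples)
#'
#' Expects the UCSC-Xena orientation: first column the gene identifier,
#' remaining columns one per sample, values log-transformed normalized
#' counts. The matrix is transposed on load to patients x genes.
#'
#' @param path TSV file.
#' @return Numeric matrix, patients in rows (named), genes in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  genes <- as.character(df[[1]])
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(mat) <- genes
  storage.mode(mat) <- "double"
  mat
}

.parse_stage_digit <- function(x, prefix) {
  d <- suppressWarnings(as.integer(sub(sprintf("^%s(\\d).*", prefix), "\\1",
                                       toupper(trimws(as.character(x))))))
  d
}

#' Load and dichotomize a clinical table
#'
#' Applies the preprocessing rules for mixed clinical covariates:
#' \itemize{
#'   \item age: `< 65` years -> 0, `>= 65` -> 1 (a pre-dichotomized
#'     `age_ge65` column passes through);
#'   \item gender: male -> 1, female -> 0 (or a 0/1 `gender` column);
#'   \item T stage: T0-2 -> 0, T3-4 -> 1;
#'   \item N stage: N0 -> 0, N1-3 -> 1; when missing, inferred from the
#'     count of positive lymph nodes (any positive -> N+);
#'   \item M stage: M0 -> 0, M1 -> 1; when missing, a recorded metastatic
#'     site of "lymph node only" implies M0.
#' }
#' Patients with missing or negative survival days, or with stage codes
#' that cannot be parsed or imputed, are dropped; all actions are counted
#' in the attached report.
#'
#' @param x A data frame or path to a TSV with columns `patient_id`,
#'   `OS_days`, `event`, and either the dichotomized covariates
#'   (`age_ge65`, `gender`, `T_pos`, `N_pos`, `M_pos`) or raw columns
#'   (`age`, `gender`, `T_stage`, `N_stage`, `M_stage`, optionally
#'   `lymph_nodes_positive`, `metastatic_site`).
#' @return List with `clinical` (a binary [feature_matrix()]), `records`
#'   (data frame `duration`, `event`), `patient_ids`, and `report` (named
#'   counts of drops and imputations).
#' @export
load_clinical <- function(x) {
  df <- if (is.character(x)) utils::read.delim(x, check.names = FALSE) else x
  stopifnot(all(c("patient_id", "OS_days", "event") %in% names(df)))
  report <- c(input = nrow(df), dropped_survival = 0L, dropped_stage = 0L,
              imputed_N = 0L, imputed_M = 0L)

  os <- suppressWarnings(as.numeric(df$OS_days))
  bad_os <- is.na(os) | os < 0
  report["dropped_survival"] <- sum(bad_os)
  df <- df[!bad_os, , drop = FALSE]
  os <- os[!bad_os]

  n <- nrow(df)
  age <- if ("age_ge65" %in% names(df)) {
    as.numeric(df$age_ge65)
  } else if ("age" %in% names(df)) {
    as.numeric(as.numeric(df$age) >= 65)
  } else stop("no age or age_ge65 column")

  gender <- if (is.numeric(df$gender)) {
    as.numeric(df$gender)
  } else {
    as.numeric(tolower(trimws(df$gender)) == "male")
  }

  if ("T_pos" %in% names(df)) {
    t_pos <- as.numeric(df$T_pos)
  } else {
    d <- .parse_stage_digit(df$T_stage, "T")
    t_pos <- ifelse(is.na(d), NA_real_, as.numeric(d >= 3))
  }

  if ("N_pos" %in% names(df)) {
    n_pos <- as.numeric(df$N_pos)
  } else {
    d <- .parse_stage_digit(df$N_stage, "N")
    n_pos <- ifelse(is.na(d), NA_real_, as.numeric(d >= 1))
    if ("lymph_nodes_positive" %in% names(df)) {
      miss <- is.na(n_pos) & !is.na(df$lymph_nodes_positive)
      n_pos[miss] <- as.numeric(df$lymph_nodes_positive[miss] > 0)
      report["imputed_N"] <- sum(miss)
    }
  }

  if ("M_pos" %in% names(df)) {
    m_pos <- as.numeric(df$M_pos)
  } else {
    d <- .parse_stage_digit(df$M_stage, "M")
    m_pos <- ifelse(is.na(d), NA_real_, as.numeric(d >= 1))
    if ("metastatic_site" %in% names(df)) {
      site <- tolower(trimws(as.character(df$metastatic_site)))
      miss <- is.na(m_pos) & site == "lymph node only"
      m_pos[miss] <- 0
      report["imputed_M"] <- sum(miss)
    }
  }

  clin <- cbind(age_ge65 = age, gender = gender, T_pos = t_pos,
                N_pos = n_pos, M_pos = m_pos)
  bad_stage <- rowSums(is.na(clin)) > 0
  if (any(bad_stage)) {
    message("load_clinical: dropping unparseable rows: ",
            paste(df$patient_id[bad_stage], collapse = ", "))
  }
  report["dropped_stage"] <- sum(bad_stage)
  keep <- !bad_stage
  clin <- clin[keep, , drop = FALSE]

  list(clinical = feature_matrix(clin, feature_kind = "binary",
                                 patient_ids = as.character(df$patient_id[keep])),
       records = data.frame(duration = os[keep],
                            event = as.integer(df$event[keep])),
       patient_ids = as.character(df$patient_id[keep]),
       report = report)
}

#' Combine expression and clinical blocks into one feature matrix
#'
#' Rows are matched by patient identifier; patients present in only one
#' block are dropped.
#'
#' @param expr Patients x genes numeric matrix (rownames = patient ids).
#' @param clinical The `clinical` element of [load_clinical()].
#' @return A [feature_matrix()] with continuous gene columns followed by
#'   binary clinical columns.
#' @export
combine_features <- function(expr, clinical) {
  ids <- intersect(rownames(expr), clinical$patient_ids)
  if (length(ids) < 3L) stop("fewer than 3 patients shared between blocks")
  e <- expr[ids, , drop = FALSE]
  c_idx <- match(ids, clinical$patient_ids)
  cl <- clinical$values[c_idx, , drop = FALSE]
  feature_matrix(cbind(e, cl),
                 feature_kind = c(rep("continuous", ncol(e)),
                                  rep("binary", ncol(cl))),
                 patient_ids = ids)
}

#' Load a cohort written by [write_cohort()] (or any Xena-style pair)
#'
#' @param expr_path Expression TSV (genes x samples).
#' @param clinical_path Clinical TSV.
#' @return List with `X` (combined [feature_matrix()]) and `records`,
#'   aligned to the same patients.
#' @export
load_cohort <- function(expr_path, clinical_path) {
  expr <- read_expression(expr_path)
  cl <- load_clinical(clinical_path)
  X <- combine_features(expr, cl$clinical)
  rec_idx <- match(X$patient_ids, cl$patient_ids)
  list(X = X, records = cl$records[rec_idx, , drop = FALSE])
}
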