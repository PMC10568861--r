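#' Read and validate an analysis dataset
#'
#' Reads a delimited table (comma- or tab-separated, chosen from the file
#' extension) and validates it for estimation: the treatment column must be
#' strictly binary 0/1, the outcome numeric, and no missing values are
#' allowed in any used column (rows are rejected, never imputed).
#'
#' @param path Path to a `.csv` / `.tsv` / `.txt` file with a header row.
#' @param treatment,outcome Column names.
#' @param covariates Optional character vector restricting the covariate
#'   columns kept (default: every other column).
#' @return A validated data frame; arm sizes are reported via `message()`.
#' @export
read_ate_data <- function(path, treatment = "Z", outcome = "Y",
                          covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty dataset: ", path)
  if (!is.null(covariates)) {
    d <- d[, unique(c(covariates, treatment, outcome)), drop = FALSE]
  }
  d <- validate_dataset(d, treatment, outcome)
  message(sprintf("read %d rows: n1 = %d treated, n0 = %d control",
                  nrow(d), sum(d[[treatment]] == 1), sum(d[[treatment]] == 0)))
  d
}

# Shared validation used by read_ate_data() and mr_ate().
validate_dataset <- function(data, treatment, outcome) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(treatment, outcome), names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  z <- data[[treatment]]
  if (!all(z %in% c(0, 1))) {
    stop(sprintf("treatment column '%s' must be strictly binary 0/1",
                 treatment))
  }
  if (!is.numeric(data[[outcome]])) {
    stop(sprintf("outcome column '%s' must be numeric", outcome))
  }
  if (anyNA(data)) {
    stop("dataset contains missing values; supply complete cases")
  }
  if (all(z == 1) || all(z == 0)) stop("one treatment arm is empty")
  data[[treatment]] <- as.integer(z)
  data
}

#' Write a results table
#'
#' Writes a tab-separated table with numeric columns rounded to three
#' decimals (table parity) and, alongside it, a `.json` sidecar holding the
#' same values at full precision.
#'
#' @param results A data frame (e.g. `fit$estimates` or `sim$summary`).
#' @param path Output TSV path; the sidecar is `path` with a `.json`
#'   extension appended.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(results, paste0(path, ".json"), dataframe = "columns",
                       digits = NA, na = "null")
  invisible(path)
}
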