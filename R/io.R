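# Delimited-text I/O for VLE datasets and fit reports.
#
# Dataset format: comment header lines starting with '#' carrying the
# component names and units, then a tab-separated table with columns
# T, P, x1..xn, y1..yn, weight; NA marks unmeasured phases.
# Units are fixed at this boundary: K, bar, mole fractions.

#' Write a VLE dataset to a delimited text file
#'
#' @param data A `vle_dataset` (or compatible data.frame).
#' @param path Output file path.
#' @param components Component names; defaults to the dataset attribute.
#' @return `path`, invisibly.
#' @export
write_vle_dataset <- function(data, path, components = attr(data, "components")) {
  if (is.null(components)) stop("component names are required to write a dataset")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cpaeos VLE dataset",
               paste("# components:", paste(components, collapse = " ")),
               "# units: T K; P bar; compositions mole fraction"), con)
  df <- as.data.frame(data)
  df[] <- lapply(df, function(v) if (is.numeric(v)) signif(v, 15) else v)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' Read a VLE dataset written by [write_vle_dataset()]
#'
#' Validates the header and the composition sums; malformed files fail
#' with a diagnostic naming the offending line or column.
#'
#' @param path Input file path.
#' @return A `vle_dataset` data.frame with attribute `components`.
#' @export
read_vle_dataset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  comp_line <- grep("^# components:", hdr, value = TRUE)
  if (length(comp_line) != 1)
    stop("malformed dataset header: expected exactly one '# components:' line in ",
         path)
  components <- strsplit(trimws(sub("^# components:", "", comp_line)), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (col in c("T", "P"))
    if (!col %in% names(df))
      stop("malformed dataset: missing required column '", col, "' in ", path)
  ncomp <- length(components)
  xcols <- paste0("x", seq_len(ncomp)); ycols <- paste0("y", seq_len(ncomp))
  if (!all(xcols %in% names(df)) && !all(ycols %in% names(df)))
    stop("malformed dataset: need composition columns ",
         paste(xcols, collapse = ","), " and/or ",
         paste(ycols, collapse = ","), " in ", path)
  if (any(df$P <= 0, na.rm = TRUE)) stop("dataset contains non-positive pressures")
  for (cols in list(xcols, ycols)) {
    if (all(cols %in% names(df))) {
      s <- rowSums(df[cols])
      bad <- which(!is.na(s) & abs(s - 1) > 1e-6)
      if (length(bad))
        stop("composition rows do not sum to 1 (data row ", bad[1],
             ", columns ", paste(cols, collapse = ","), ")")
    }
  }
  has_any <- rep(FALSE, nrow(df))
  if (all(xcols %in% names(df))) has_any <- has_any | !is.na(df[[xcols[1]]])
  if (all(ycols %in% names(df))) has_any <- has_any | !is.na(df[[ycols[1]]])
  if (!all(has_any))
    stop("data row ", which(!has_any)[1], " reports neither phase composition")
  structure(df, components = components,
            class = c("vle_dataset", "data.frame"))
}

#' Write a human-readable fit report
#'
#' @param fit A `cpa_fit` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "cpa_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# cpaeos fit report:", fit$description),
               paste0(names(fit$parameters), "\t",
                      format(fit$parameters, digits = 10)),
               paste0("objective\t", format(fit$objective, digits = 10)),
               if (length(fit$aad))
                 paste0("aad_", names(fit$aad), "_pct\t",
                        format(fit$aad, digits = 6)),
               paste0("evaluations\t", fit$evaluations),
               paste0("converged\t", fit$converged)), con)
  invisible(path)
}
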