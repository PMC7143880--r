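# Concordance of cluster-repertoire conservation (RC) with genome-based
# species delimitation across strain pairs. Species boundaries follow the
# standard criteria: digital DNA-DNA hybridization (dDDH) >= 70% for the
# same genomic species, average nucleotide identity (ANI) >= 95% as the
# fallback when dDDH is unavailable.

#' Species call for one strain pair
#'
#' @param dDDH digital DNA-DNA hybridization percentage, or `NA`.
#' @param ANI average nucleotide identity percentage, or `NA`.
#' @param ddh_cutoff dDDH species boundary (default 70, inclusive).
#' @param ani_cutoff ANI species boundary (default 95, inclusive).
#' @return `"same"`, `"different"` or `"undetermined"` (both inputs `NA`).
#' @export
classify_species <- function(dDDH = NA_real_, ANI = NA_real_,
                             ddh_cutoff = 70, ani_cutoff = 95) {
  if (!is.na(dDDH)) return(if (dDDH >= ddh_cutoff) "same" else "different")
  if (!is.na(ANI)) return(if (ANI >= ani_cutoff) "same" else "different")
  "undetermined"
}

#' Read a strain-pair table
#'
#' TSV with columns `pair_id`, `sim16S`, `dDDH`, `ANI`, `RC` (percentages;
#' empty/NA allowed); a `species_call` column is recomputed from dDDH/ANI.
#'
#' @param path TSV path; `#` comments allowed.
#' @inheritParams classify_species
#' @return a data frame with an added `species_call` column.
#' @export
read_pair_table <- function(path, ddh_cutoff = 70, ani_cutoff = 95) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pair_id", "sim16S", "dDDH", "ANI", "RC")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    bgc_stop("bgcrep_format_error",
             sprintf("%s: missing column(s) %s", path,
                     paste(missing_cols, collapse = ", ")))
  }
  for (cc in c("sim16S", "dDDH", "ANI", "RC")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(!is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] > 100))) {
      bgc_stop("bgcrep_format_error",
               sprintf("%s: %s outside [0, 100]", path, cc))
    }
  }
  df$species_call <- mapply(classify_species, df$dDDH, df$ANI,
                            MoreArgs = list(ddh_cutoff = ddh_cutoff,
                                            ani_cutoff = ani_cutoff))
  df
}

#' Least-squares regression between two pair-table variables
#'
#' Ordinary least squares of `yvar` on `xvar` over the complete-case subset
#' of the records, as used to relate RC to dDDH or 16S similarity across
#' strain pairs.
#'
#' @param records data frame of strain-pair records.
#' @param xvar,yvar column names.
#' @return a `bgc_regression` list: `n`, `slope`, `intercept`, `r`,
#'   `r_squared`.
#' @export
regress_pairs <- function(records, xvar, yvar) {
  stopifnot(xvar %in% names(records), yvar %in% names(records))
  x <- records[[xvar]]; y <- records[[yvar]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    bgc_stop("bgcrep_insufficient_data",
             sprintf("need >= 3 complete cases of (%s, %s), have %d",
                     xvar, yvar, sum(ok)))
  }
  x <- x[ok]; y <- y[ok]
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)
  structure(list(n = length(x),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, r_squared = r^2,
                 xvar = xvar, yvar = yvar),
            class = "bgc_regression")
}

#' @export
print.bgc_regression <- function(x, ...) {
  cat(sprintf("<regression> %s ~ %s, n = %d\n", x$yvar, x$xvar, x$n))
  cat(sprintf("  slope %.4f, intercept %.4f, r = %.4f, R^2 = %.4f\n",
              x$slope, x$intercept, x$r, x$r_squared))
  invisible(x)
}
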