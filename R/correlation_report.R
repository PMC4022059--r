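# Structure-vs-digestibility correlation reporting: one summary row per
# sample (composition, digestibility, and the image-derived structural
# parameters), correlated parameter-by-parameter against a response.

#' Structural/compositional parameters correlated against digestibility
#' @export
structural_parameters <- c("xylan", "lignin", "degree_of_polymerization",
                           "particle_size", "aspect_ratio",
                           "cell_wall_thickness", "surface_roughness",
                           "delamination_porosity")

#' Pearson product-moment correlation
#'
#' Implemented directly from the product-moment formula; symmetric in its
#' arguments and bounded by \[-1, 1\].
#'
#' @param x,y numeric vectors of equal length `>= 2`; both must be
#'   non-constant (the correlation is undefined otherwise).
#' @return the correlation coefficient R.
#' @examples
#' pearson_r(c(68.7, 88.0, 95.2), c(8.8, 4.8, 3.2))  # ~ -1.00
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("correlation undefined for a constant series")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

#' Per-sample morphometric and digestibility summaries for pretreated corn
#' stover
#'
#' The package's bundled example dataset: one row per sample condition
#' (untreated control plus corn stover dilute-acid pretreated at identical
#' nominal severity in three reactor configurations -- ZipperClave (ZC),
#' steam gun (SG), and horizontal screw (HS)), with composition (% xylan,
#' % lignin), cellulose degree of polymerization, 96-h enzymatic glucan
#' release (%), and the four image-derived structural parameters: mean
#' particle area (mm^2), mean particle aspect ratio, mean cell wall thickness
#' (um), SEM surface roughness (grayscale SD units), and intra-wall
#' delamination/porosity area (%).
#'
#' @return a data frame with one row per sample.
#' @export
reactor_morphometrics <- function() {
  path <- system.file("extdata", "reactor_morphometrics.csv",
                      package = "stovermorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

is_control_sample <- function(ids) {
  grepl("untreat|control|native", ids, ignore.case = TRUE)
}

#' Correlate structural parameters against digestibility
#'
#' For each structural/compositional parameter, the Pearson R (and R^2) of
#' the parameter against the response across the chosen sample set.  The
#' default set, `"pretreated-only"`, excludes control/untreated rows:
#' the untreated feedstock is not a point on the pretreatment
#' severity-response surface, and several parameters (notably cell wall
#' thickness, which increases on pretreatment by wall swelling but decreases
#' with digestibility among pretreated samples) correlate in opposite
#' directions with and without it.
#'
#' Parameters with missing values are correlated over their complete rows;
#' parameters left with fewer than 2 usable rows, or constant series, yield
#' `NA` rather than an error.
#'
#' @param summaries data frame with a `sample_id` column, the response
#'   column, and parameter columns (see [reactor_morphometrics()] for the
#'   schema).
#' @param response response column name (default `"glucan_release"`).
#' @param sample_set `"pretreated-only"` (drop rows whose `sample_id`
#'   matches untreated/control/native, case-insensitively) or `"all"`.
#' @param parameters parameter column names to correlate; defaults to the
#'   [structural_parameters] present in `summaries`.
#' @return a `correlation_table`: data frame with `parameter`, `r`,
#'   `r_squared`, `n`; attributes `response`, `sample_set`, `samples_used`.
#' @export
build_correlation_table <- function(summaries, response = "glucan_release",
                                    sample_set = c("pretreated-only", "all"),
                                    parameters = NULL) {
  sample_set <- match.arg(sample_set)
  stopifnot(is.data.frame(summaries), response %in% names(summaries))
  if (is.null(parameters))
    parameters <- intersect(structural_parameters, names(summaries))
  if (length(parameters) == 0L) stop("no parameter columns found")
  keep <- if (sample_set == "pretreated-only" && "sample_id" %in% names(summaries))
    !is_control_sample(summaries$sample_id) else rep(TRUE, nrow(summaries))
  dat <- summaries[keep, , drop = FALSE]
  if (nrow(dat) < 2L)
    stop(sprintf("fewer than 2 usable rows in sample set '%s'", sample_set))
  y <- dat[[response]]
  res <- lapply(parameters, function(p) {
    x <- dat[[p]]
    ok <- is.finite(x) & is.finite(y)
    r <- if (sum(ok) >= 2L && stats::var(x[ok]) > 0 && stats::var(y[ok]) > 0)
      pearson_r(x[ok], y[ok]) else NA_real_
    data.frame(parameter = p, r = r, r_squared = r^2, n = sum(ok))
  })
  out <- do.call(rbind, res)
  attr(out, "response") <- response
  attr(out, "sample_set") <- sample_set
  attr(out, "samples_used") <- if ("sample_id" %in% names(dat))
    dat$sample_id else as.character(seq_len(nrow(dat)))
  class(out) <- c("correlation_table", "data.frame")
  out
}

round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Write a correlation report
#'
#' Emits the correlation table as CSV (unrounded values plus 2-decimal
#' display columns, rounded half away from zero) and optionally as an
#' aligned plain-text table, both carrying provenance metadata (response,
#' sample set, samples used, n per parameter).
#'
#' @param table a `correlation_table` from [build_correlation_table()].
#' @param csv_path output CSV path.
#' @param txt_path optional output text path.
#' @return the display data frame, invisibly.
#' @export
render_report <- function(table, csv_path, txt_path = NULL) {
  stopifnot(inherits(table, "correlation_table"))
  disp <- data.frame(parameter = table$parameter,
                     r = table$r, r_squared = table$r_squared, n = table$n,
                     r_2dp = round_half_up(table$r, 2),
                     r_squared_2dp = round_half_up(table$r_squared, 2))
  meta <- sprintf("# response: %s | sample set: %s | samples: %s",
                  attr(table, "response"), attr(table, "sample_set"),
                  paste(attr(table, "samples_used"), collapse = ", "))
  con <- file(csv_path, "w")
  writeLines(meta, con)
  utils::write.csv(disp, con, row.names = FALSE)
  close(con)
  if (!is.null(txt_path)) {
    lines <- c(meta, sprintf("%-26s %8s %8s %4s", "parameter", "R", "R^2", "n"),
               sprintf("%-26s %8s %8s %4d", disp$parameter,
                       ifelse(is.na(disp$r_2dp), "NA", sprintf("%.2f", disp$r_2dp)),
                       ifelse(is.na(disp$r_squared_2dp), "NA",
                              sprintf("%.2f", disp$r_squared_2dp)),
                       disp$n))
    writeLines(lines, txt_path)
  }
  invisible(disp)
}

#' Re-read a rendered correlation CSV
#'
#' @param csv_path path written by [render_report()].
#' @return the display data frame (metadata comment line skipped).
#' @export
read_report <- function(csv_path) {
  utils::read.csv(csv_path, comment.char = "#", stringsAsFactors = FALSE)
}
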