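#' Construct a diary dataset
#'
#' Wraps a long-format data frame (one row per subject x occasion) with the
#' column roles needed by the models: a subject identifier, an integer
#' occasion index, and either a single outcome column (manifest mode) or a
#' set of item-response columns (latent mode).  Occasion-varying covariates
#' and subject-level (time-invariant) covariates are declared by name.
#'
#' Occasions are 1-based integers, unique within subject, and need not be
#' contiguous: the models carry no time trend, so only row membership
#' matters.  Missing outcome/item cells are retained (coded \code{NA}) and
#' masked at likelihood evaluation time under a missing-at-random
#' assumption; subject-level covariates must be constant within subject.
#'
#' @param df data frame in long format.
#' @param subject name of the subject-identifier column.
#' @param occasion name of the integer occasion column.
#' @param outcome name of the single outcome column (manifest mode), or
#'   \code{NULL} in latent mode.
#' @param items character vector of item-response column names (latent
#'   mode), or \code{NULL} in manifest mode.
#' @param x character vector of occasion-varying covariate columns.
#' @param w character vector of subject-level covariate columns.
#' @return An object of class \code{diary_data}: the data frame sorted by
#'   subject and occasion, with the column roles stored as attributes.
#' @seealso [read_diary_csv()], [person_center()], [simulate_melsm()]
#' @export
diary_data <- function(df, subject = "subject", occasion = "occasion",
                       outcome = NULL, items = NULL,
                       x = character(), w = character()) {
  stopifnot(is.data.frame(df))
  need <- c(subject, occasion, outcome, items, x, w)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "))
  if (is.null(outcome) && is.null(items))
    stop("supply either an `outcome` column (manifest) or `items` (latent)")
  if (!is.null(outcome) && !is.null(items))
    stop("supply `outcome` or `items`, not both")

  df <- as.data.frame(df)
  occ <- df[[occasion]]
  if (any(is.na(occ)) || any(occ != as.integer(occ)) || any(occ < 1))
    stop("`occasion` must hold positive integers (1-based)")
  df[[occasion]] <- as.integer(occ)

  for (v in c(outcome, items, x, w))
    if (!is.numeric(df[[v]]))
      stop("column `", v, "` must be numeric")

  key <- paste(df[[subject]], df[[occasion]], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (subject, occasion) rows: ",
         paste(gsub("\r", ":", utils::head(dup, 5L)), collapse = ", "))
  }
  df <- df[order(df[[subject]], df[[occasion]]), , drop = FALSE]
  rownames(df) <- NULL

  ## subject-level covariates must be constant within subject
  for (v in w) {
    rng <- tapply(df[[v]], df[[subject]], function(z) diff(range(z)))
    if (any(rng > 1e-10, na.rm = TRUE))
      stop("subject-level covariate `", v, "` varies within subject")
  }

  structure(df, class = c("diary_data", "data.frame"),
            subject = subject, occasion = occasion,
            outcome = outcome, items = items, x = x, w = w)
}

dd_attr <- function(data, which) attr(data, which, exact = TRUE)

#' @export
print.diary_data <- function(x, ...) {
  sid <- x[[dd_attr(x, "subject")]]
  cat(sprintf("<diary_data> %d subjects, %d rows, mode: %s\n",
              length(unique(sid)), nrow(x),
              if (is.null(dd_attr(x, "items"))) "manifest" else
                sprintf("latent (%d items)", length(dd_attr(x, "items")))))
  NextMethod()
  invisible(x)
}

#' Read a long-format diary CSV
#'
#' Comma-separated, header required, UTF-8; empty cells and \code{"NA"} are
#' treated as missing.  The schema maps column roles to column names, as in
#' \code{list(subject = "id", occasion = "day", items = c("y1","y2"))}.
#'
#' @param path path to the CSV file.
#' @param schema named list with entries \code{subject}, \code{occasion},
#'   and \code{outcome} or \code{items}, plus optional \code{x} and
#'   \code{w} covariate names.
#' @return A [diary_data] object.
#' @export
read_diary_csv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = c("NA", ""), fileEncoding = "UTF-8")
  diary_data(df,
             subject = schema$subject %||% "subject",
             occasion = schema$occasion %||% "occasion",
             outcome = schema$outcome,
             items = schema$items,
             x = schema$x %||% character(),
             w = schema$w %||% character())
}

#' Write a diary dataset to CSV
#'
#' Inverse of [read_diary_csv()]: on complete data, write-then-read
#' reproduces the dataset field by field.
#'
#' @param data a [diary_data] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_diary_csv <- function(data, path) {
  stopifnot(inherits(data, "diary_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Person-mean centering of an occasion-varying covariate
#'
#' Splits a covariate into its person mean (computed from that subject's
#' observed occasions only) and the within-person deviation from that mean,
#' appending columns \code{<var>_pm} and \code{<var>_pmc}.  The deviation
#' column sums to zero within every subject, so the two columns carry the
#' between- and within-subject parts of the covariate respectively.
#'
#' @param data a [diary_data] object.
#' @param var name of the covariate column to centre.
#' @return The dataset with the two derived columns added; \code{<var>_pm}
#'   is registered as a subject-level covariate and \code{<var>_pmc} as an
#'   occasion-varying one.
#' @export
person_center <- function(data, var) {
  stopifnot(inherits(data, "diary_data"))
  if (!var %in% names(data)) stop("no such column: ", var)
  sid <- data[[dd_attr(data, "subject")]]
  pm <- stats::ave(data[[var]], sid, FUN = function(z) mean(z, na.rm = TRUE))
  df <- as.data.frame(data)
  df[[paste0(var, "_pm")]] <- pm
  df[[paste0(var, "_pmc")]] <- df[[var]] - pm
  diary_data(df,
             subject = dd_attr(data, "subject"),
             occasion = dd_attr(data, "occasion"),
             outcome = dd_attr(data, "outcome"),
             items = dd_attr(data, "items"),
             x = union(dd_attr(data, "x"), paste0(var, "_pmc")),
             w = union(dd_attr(data, "w"), paste0(var, "_pm")))
}
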