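#' Constraint map for measurement parameters
#'
#' An items x occasions character matrix of parameter labels: cells sharing
#' a label share one free parameter.  \code{by = "item"} gives parameters
#' equal across occasions within item (full invariance for that block),
#' \code{by = "cell"} gives every (item, occasion) cell its own parameter
#' (configural), and \code{by = "single"} shares one parameter everywhere.
#'
#' @param n_items number of items M.
#' @param n_occasions number of occasions T.
#' @param by sharing pattern.
#' @param prefix label prefix.
#' @return A character matrix of labels.
#' @export
constraint_map <- function(n_items, n_occasions,
                           by = c("item", "cell", "single"), prefix = "p") {
  by <- match.arg(by)
  lab <- switch(by,
    item = matrix(paste0(prefix, seq_len(n_items)), n_items, n_occasions),
    cell = matrix(paste0(prefix, rep(seq_len(n_items), n_occasions), ".t",
                         rep(seq_len(n_occasions), each = n_items)),
                  n_items, n_occasions),
    single = matrix(paste0(prefix, "1"), n_items, n_occasions))
  lab
}

#' Free individual cells of a constraint map
#'
#' Gives the listed (item, occasion) cells their own unique labels,
#' detaching them from whatever parameter they shared.  Used to relax an
#' equality constraint for specific item/day combinations.
#'
#' @param map a constraint map matrix.
#' @param cells two-column matrix (or list of length-2 vectors) of
#'   (item, occasion) indices.
#' @return The modified map.
#' @export
free_cells <- function(map, cells) {
  if (is.list(cells)) cells <- do.call(rbind, cells)
  cells <- matrix(as.integer(cells), ncol = 2L)
  for (r in seq_len(nrow(cells)))
    map[cells[r, 1], cells[r, 2]] <-
      paste0("free", cells[r, 1], ".t", cells[r, 2])
  map
}

#' Longitudinal measurement model specification
#'
#' Confirmatory factor model linking M items per occasion to the
#' occasion-specific latent variable, identified by an anchor item whose
#' intercept is fixed to 0 and loading to 1 at every occasion, so the
#' latent variable carries the anchor item's scale over time.  Equality of
#' intercepts, loadings and uniquenesses across occasions is controlled by
#' constraint maps (see [constraint_map()]); anchor intercept/loading cells
#' are fixed regardless of the maps.
#'
#' @param n_items number of items per occasion.
#' @param n_occasions number of occasions.
#' @param anchor index of the anchor item (default 1).
#' @param intercepts,loadings,uniquenesses constraint maps, or one of the
#'   [constraint_map()] keywords (default \code{"item"}: full invariance).
#' @return A \code{measurement_spec} object.
#' @export
measurement_spec <- function(n_items, n_occasions, anchor = 1L,
                             intercepts = "item", loadings = "item",
                             uniquenesses = "item") {
  as_map <- function(m, prefix) {
    if (is.character(m) && length(m) == 1L)
      m <- constraint_map(n_items, n_occasions, m, prefix)
    m <- as.matrix(m)
    if (!all(dim(m) == c(n_items, n_occasions)))
      stop("constraint map must be ", n_items, " x ", n_occasions)
    if (any(is.na(m)) || any(!nzchar(m)))
      stop("constraint map is not a partition: every cell needs a label")
    m
  }
  stopifnot(n_items >= 1L, n_occasions >= 1L,
            anchor >= 1L, anchor <= n_items)
  spec <- structure(list(
    n_items = as.integer(n_items), n_occasions = as.integer(n_occasions),
    anchor = as.integer(anchor),
    intercept_map = as_map(intercepts, "tau"),
    loading_map = as_map(loadings, "lam"),
    uniq_map = as_map(uniquenesses, "psi")), class = "measurement_spec")
  spec
}

## free labels per block, in first-appearance order; anchor cells of the
## intercept/loading maps are fixed (0 / 1) and carry no parameter
measurement_labels <- function(spec) {
  anchor_rowless <- function(map) map[-spec$anchor, , drop = FALSE]
  list(intercepts = unique(as.vector(t(anchor_rowless(spec$intercept_map)))),
       loadings = unique(as.vector(t(anchor_rowless(spec$loading_map)))),
       uniquenesses = unique(as.vector(t(spec$uniq_map))))
}

#' Number of free measurement parameters
#'
#' Counts the distinct parameter labels over the intercept, loading and
#' uniqueness constraint maps (anchor intercept/loading cells are fixed and
#' not counted).  Differences in this count give the degrees of freedom of
#' nested measurement-invariance comparisons.
#'
#' @param spec a [measurement_spec].
#' @return Integer count.
#' @export
n_free_measurement <- function(spec) {
  lab <- measurement_labels(spec)
  sum(lengths(lab))
}

#' Pack measurement parameter tables into the free-parameter vector
#'
#' Maps full items x occasions tables of intercepts, loadings and
#' uniquenesses to the vector of free parameters defined by the constraint
#' maps.  Per-item vectors are accepted and recycled across occasions.
#' Cells sharing a label must agree; \code{unpack_measurement} is the exact
#' inverse on the free vector.
#'
#' @param spec a [measurement_spec].
#' @param tau,lambda,psi full M x T tables (or length-M vectors).
#' @return Named numeric vector of free parameters (uniquenesses on the
#'   natural, positive scale).
#' @export
pack_measurement <- function(spec, tau, lambda, psi) {
  M <- spec$n_items; Tn <- spec$n_occasions
  expand <- function(v) if (is.matrix(v)) v else matrix(v, M, Tn)
  tau <- expand(tau); lambda <- expand(lambda); psi <- expand(psi)
  lab <- measurement_labels(spec)
  pick <- function(map, tab, labels, drop_anchor) {
    if (drop_anchor) { map <- map[-spec$anchor, , drop = FALSE]
                       tab <- tab[-spec$anchor, , drop = FALSE] }
    out <- vapply(labels, function(l) {
      vals <- tab[map == l]
      if (diff(range(vals)) > 1e-8)
        stop("cells sharing label `", l, "` hold unequal values")
      vals[1]
    }, numeric(1))
    out
  }
  c(stats::setNames(pick(spec$intercept_map, tau, lab$intercepts, TRUE),
                    paste0("tau.", lab$intercepts, recycle0 = TRUE)),
    stats::setNames(pick(spec$loading_map, lambda, lab$loadings, TRUE),
                    paste0("lambda.", lab$loadings, recycle0 = TRUE)),
    stats::setNames(pick(spec$uniq_map, psi, lab$uniquenesses, FALSE),
                    paste0("psi.", lab$uniquenesses, recycle0 = TRUE)))
}

#' @rdname pack_measurement
#' @param free named free-parameter vector as produced by
#'   \code{pack_measurement}.
#' @return \code{unpack_measurement}: list of full M x T tables
#'   \code{tau}, \code{lambda}, \code{psi} with the anchor row fixed at
#'   intercept 0 and loading 1.
#' @export
unpack_measurement <- function(free, spec) {
  M <- spec$n_items; Tn <- spec$n_occasions
  lab <- measurement_labels(spec)
  fill <- function(map, labels, prefix, fixed_val) {
    tab <- matrix(NA_real_, M, Tn)
    for (l in labels) tab[map == l] <- free[[paste0(prefix, l)]]
    if (!is.null(fixed_val)) tab[spec$anchor, ] <- fixed_val
    tab
  }
  list(tau = fill(spec$intercept_map, lab$intercepts, "tau.", 0),
       lambda = fill(spec$loading_map, lab$loadings, "lambda.", 1),
       psi = fill(spec$uniq_map, lab$uniquenesses, "psi.", NULL))
}

#' Block-diagonal loading matrix for one subject
#'
#' Builds the stacked loading matrix mapping the occasion-specific latent
#' variables to the observed item responses: one block column per occasion
#' present, holding that occasion's item-loading column, with rows for
#' unobserved items removed.  Every row has exactly one nonzero entry.
#'
#' @param spec a [measurement_spec].
#' @param lambda full M x T loading table (or length-M vector), e.g. from
#'   [unpack_measurement()].
#' @param occasions occasion indices present for the subject.
#' @param obs optional M x length(occasions) logical matrix of observed
#'   cells (default all observed).  Each occasion must retain the anchor.
#' @return The (observed cells) x length(occasions) loading matrix.
#' @export
build_lambda <- function(spec, lambda, occasions = seq_len(spec$n_occasions),
                         obs = NULL) {
  M <- spec$n_items
  if (!is.matrix(lambda)) lambda <- matrix(lambda, M, spec$n_occasions)
  Tn <- length(occasions)
  if (is.null(obs)) obs <- matrix(TRUE, M, Tn)
  if (any(!obs[spec$anchor, ]))
    stop("an occasion is missing the anchor item: latent scale unidentified")
  lam <- lambda[, occasions, drop = FALSE]
  lam[spec$anchor, ] <- 1
  L <- matrix(0, sum(obs), Tn)
  r <- 0L
  for (t in seq_len(Tn)) for (m in seq_len(M)) if (obs[m, t]) {
    r <- r + 1L
    L[r, t] <- lam[m, t]
  }
  L
}

#' Sequential measurement-invariance testing
#'
#' Fits the ladder of measurement models — configural, equal loadings,
#' equal intercepts, equal loadings and intercepts, and additionally equal
#' uniquenesses — and compares them by likelihood-ratio tests whose degrees
#' of freedom equal the differences in free-parameter counts.  Each
#' equality model is tested against the configural model; the equal-
#' uniquenesses model is tested against the equal-loadings-and-intercepts
#' model.  The structural model during these fits is an intercept-only
#' location scale model without the random scale effect.
#'
#' @param data a latent-mode [diary_data] object.
#' @param n_items,n_occasions,anchor measurement layout (defaults inferred
#'   from the data).
#' @param free_intercepts_equal optional (item, occasion) cells freed in
#'   the equal-intercepts model.
#' @param free_intercepts_both optional cells freed in the combined model.
#' @param fit_fn function \code{(data, spec) -> melsm_fit}; defaults to
#'   [fit_melsm()] without standard errors.  Pass \code{NULL} to skip the
#'   fits and return the parameter-count bookkeeping only.
#' @return A data frame with one row per model: label, free measurement
#'   parameters, deviance, BIC, LRT statistic, df and p-value against the
#'   reference model.
#' @export
invariance_sequence <- function(data, n_items = NULL, n_occasions = NULL,
                                anchor = 1L,
                                free_intercepts_equal = NULL,
                                free_intercepts_both = NULL,
                                fit_fn = default_invariance_fit) {
  items <- dd_attr(data, "items")
  n_items <- n_items %||% length(items)
  n_occasions <- n_occasions %||% max(data[[dd_attr(data, "occasion")]])
  if (n_occasions < 2L) stop("invariance testing needs at least 2 occasions")

  eq_int_map <- constraint_map(n_items, n_occasions, "item", "tau")
  if (!is.null(free_intercepts_equal))
    eq_int_map <- free_cells(eq_int_map, free_intercepts_equal)
  both_int_map <- constraint_map(n_items, n_occasions, "item", "tau")
  if (!is.null(free_intercepts_both))
    both_int_map <- free_cells(both_int_map, free_intercepts_both)

  mspec <- function(int, load, uniq)
    measurement_spec(n_items, n_occasions, anchor, int, load, uniq)
  models <- list(
    configural = mspec("cell", "cell", "cell"),
    equal_loadings = mspec("cell", "item", "cell"),
    equal_intercepts = mspec(eq_int_map, "cell", "cell"),
    equal_loadings_intercepts = mspec(both_int_map, "item", "cell"),
    equal_uniquenesses = mspec(both_int_map, "item", "item"))
  reference <- c(configural = NA, equal_loadings = "configural",
                 equal_intercepts = "configural",
                 equal_loadings_intercepts = "configural",
                 equal_uniquenesses = "equal_loadings_intercepts")

  counts <- vapply(models, n_free_measurement, integer(1))
  out <- data.frame(model = names(models), n_free_measurement = counts,
                    deviance = NA_real_, bic = NA_real_,
                    reference = unname(reference),
                    lrt = NA_real_, df = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  fits <- NULL
  if (!is.null(fit_fn)) {
    fits <- lapply(models, function(m) {
      spec <- melsm_spec(location_spec(), between_spec(),
                         within_spec(random_scale = FALSE), measurement = m)
      fit_fn(data, spec)
    })
    out$deviance <- vapply(fits, function(f) f$deviance, numeric(1))
    out$bic <- vapply(fits, function(f) f$bic, numeric(1))
  }
  for (i in seq_len(nrow(out))) {
    ref <- out$reference[i]
    if (is.na(ref)) next
    j <- match(ref, out$model)
    out$df[i] <- counts[[j]] - counts[[i]]
    if (out$df[i] < 0L)
      stop("model `", out$model[i], "` is not nested in `", ref, "`")
    if (!is.null(fits)) {
      tst <- lrt(out$deviance[i], out$deviance[j], out$df[i])
      out$lrt[i] <- tst$statistic; out$p[i] <- tst$p
    }
  }
  attr(out, "fits") <- fits
  out
}

default_invariance_fit <- function(data, spec)
  fit_melsm(data, spec, se = FALSE)
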