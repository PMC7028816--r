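new_design <- function(mat, includes_intercept, spline = NULL) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)),
            !anyDuplicated(colnames(mat)))
  structure(list(matrix = mat, names = colnames(mat),
                 includes_intercept = includes_intercept, spline = spline),
            class = "cf_design")
}

#' @export
print.cf_design <- function(x, ...) {
  cat("<cf_design> ", nrow(x$matrix), " x ", ncol(x$matrix), " [",
      paste(utils::head(x$names, 6), collapse = ", "),
      if (ncol(x$matrix) > 6) ", ..." else "", "]",
      if (!is.null(x$spline)) paste0(" + ", ncol(x$spline$Z), " spline cols"),
      "\n", sep = "")
  invisible(x)
}

design_ncol <- function(d) ncol(d$matrix) + if (is.null(d$spline)) 0L else ncol(d$spline$Z)

#' Design matrix for the search-frequency counterfactual
#'
#' Intercept, one main effect per reference species, and all pairwise
#' (first-order) interactions between the reference series: with `k`
#' references the design has `1 + k + k(k-1)/2` columns. Main effects appear
#' in name-sorted order and interactions in name-sorted pair order, so the
#' layout is deterministic.
#'
#' @param panel A proportion [panel()] with at least one reference column.
#' @return A design-matrix object (class `cf_design`).
#' @export
build_search_design <- function(panel) {
  stopifnot(inherits(panel, "cf_panel"))
  refs <- sort(attr(panel, "ref_cols"))
  if (length(refs) == 0) abort("search design needs at least one reference")
  R <- as.matrix(panel[, refs, drop = FALSE])
  cols <- list(intercept = rep(1, nrow(R)))
  for (nm in refs) cols[[nm]] <- R[, nm]
  if (length(refs) >= 2) {
    prs <- utils::combn(refs, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      cols[[paste0(a, ":", b)]] <- R[, a] * R[, b]
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  new_design(mat, includes_intercept = TRUE)
}

#' Design matrix for the import-count counterfactual
#'
#' Intercept plus one main effect per reference species (raw counts, no
#' interactions), columns in the panel's reference order.
#'
#' @param panel A count [panel()] with at least one reference column.
#' @return A design-matrix object (class `cf_design`).
#' @export
build_import_design <- function(panel) {
  stopifnot(inherits(panel, "cf_panel"))
  refs <- attr(panel, "ref_cols")
  if (length(refs) == 0) abort("import design needs at least one reference")
  mat <- cbind(intercept = rep(1, nrow(panel)),
               as.matrix(panel[, refs, drop = FALSE]))
  new_design(mat, includes_intercept = TRUE)
}

#' Drop reference series dominated by zeros
#'
#' Reference count series that are mostly zeros carry almost no signal for a
#' counterfactual regression and destabilise the fit; any reference column
#' whose fraction of zero entries exceeds `threshold` is removed (with a
#' message naming it).
#'
#' @param panel A count [panel()].
#' @param threshold Maximum tolerated zero fraction. Default 0.5.
#' @return The panel without the zero-dominated reference columns; the
#'   dropped names are attached as attribute `dropped_refs`.
#' @export
exclude_zero_dominated <- function(panel, threshold = 0.5) {
  stopifnot(inherits(panel, "cf_panel"))
  refs <- attr(panel, "ref_cols")
  zfrac <- vapply(refs, function(nm) mean(panel[[nm]] == 0), numeric(1))
  drop <- refs[zfrac > threshold]
  if (length(drop) == length(refs)) {
    abort("all reference series are zero-dominated; nothing left to fit")
  }
  if (length(drop) > 0) {
    inform(paste0("excluding zero-dominated reference series: ",
                  paste(drop, collapse = ", ")))
  }
  keep <- setdiff(refs, drop)
  out <- panel_rows(panel, seq_len(nrow(panel)))
  out <- out[, c("date", attr(panel, "focal_col"), keep)]
  out <- structure(out,
                   class = class(panel),
                   focal_col = attr(panel, "focal_col"), ref_cols = keep,
                   frequency = attr(panel, "frequency"),
                   outcome_kind = attr(panel, "outcome_kind"))
  attr(out, "dropped_refs") <- drop
  out
}

#' Penalized cubic B-spline basis over standardized time
#'
#' Builds a cubic B-spline basis with `num_basis` functions on equally spaced
#' knots spanning the fitting-period range of standardized time. Columns are
#' centred to be orthogonal to the intercept over the fitting points, and the
#' basis is used in mixed-model form: the spline coefficients are exchangeable
#' draws from `Normal(0, spline_sd)`, with the single smoothness ("wiggliness")
#' standard deviation carrying a Half-Student-t(3, 0, 2) prior. Evaluation
#' beyond the fitting range extends each basis function linearly from its
#' boundary value and slope, so forecasts do not oscillate outside the
#' training window.
#'
#' @param t_std Standardized times of the fitting period (see
#'   [standardize_time()]).
#' @param num_basis Number of basis functions, at least 4. Default 10.
#' @return An object of class `cf_spline_basis` with the fitted-period basis
#'   matrix in `$Z`; evaluate at new times with [spline_basis_eval()].
#' @export
spline_basis <- function(t_std, num_basis = 10) {
  if (num_basis < 4) abort("num_basis must be at least 4")
  if (any(!is.finite(t_std))) abort("t_std must be finite")
  lo <- min(t_std); hi <- max(t_std)
  if (hi <= lo) abort("t_std is degenerate (single support point)")
  inner <- seq(lo, hi, length.out = num_basis - 2)
  knots <- c(rep(lo, 3), inner, rep(hi, 3))
  raw <- splines::splineDesign(knots, t_std, ord = 4)
  centers <- colMeans(raw)
  obj <- structure(list(knots = knots, num_basis = num_basis,
                        lo = lo, hi = hi, centers = centers),
                   class = "cf_spline_basis")
  obj$Z <- spline_basis_eval(obj, t_std)
  obj
}

#' Evaluate a spline basis at new standardized times
#'
#' Times inside the fitting range use the B-spline basis directly; times
#' outside use linear extension from the boundary value and slope.
#'
#' @param basis A [spline_basis()].
#' @param t_std Standardized times at which to evaluate.
#' @param raw If `TRUE`, skip the intercept-orthogonalizing centring.
#' @return A matrix with `length(t_std)` rows and `num_basis` columns.
#' @export
spline_basis_eval <- function(basis, t_std, raw = FALSE) {
  stopifnot(inherits(basis, "cf_spline_basis"))
  t_in <- pmin(pmax(t_std, basis$lo), basis$hi)
  B <- splines::splineDesign(basis$knots, t_in, ord = 4)
  out_lo <- t_std < basis$lo
  out_hi <- t_std > basis$hi
  if (any(out_lo | out_hi)) {
    D <- splines::splineDesign(basis$knots, t_in, ord = 4, derivs = 1)
    ext <- (t_std - t_in)
    B <- B + D * ext  # linear extension; zero inside the range
  }
  if (!raw) B <- sweep(B, 2, basis$centers)
  colnames(B) <- paste0("s", seq_len(basis$num_basis))
  B
}

# month dummy design: intercept + 11 dummies, January as base month
month_design <- function(dates) {
  m <- as.POSIXlt(dates)$mon + 1L  # 1..12
  mat <- matrix(0, length(m), 12)
  mat[, 1] <- 1
  for (j in 2:12) mat[, j] <- as.numeric(m == j)
  colnames(mat) <- c("intercept", paste0("month_", month.abb[2:12]))
  mat
}

#' Design for the seasonal-trend (visitation) model
#'
#' Fixed part: intercept and 11 month dummies with January as the base month.
#' Smooth part: a penalized cubic B-spline over standardized decimal time
#' (centred and scaled by the pre-intervention period). Post-intervention rows
#' must be built with `std_time`/`basis` frozen from the fitting period.
#'
#' @param dates Dates of the rows to build.
#' @param std_time A [standardize_time()] object fitted to the pre period.
#' @param basis A [spline_basis()] built on the pre-period standardized times;
#'   if `NULL`, one is built from `dates` (fitting-period call).
#' @param num_basis Basis dimension when `basis` is built here.
#' @return A design-matrix object (class `cf_design`) whose `$spline` holds
#'   the basis object and evaluated spline columns `Z`.
#' @export
build_seasonal_design <- function(dates, std_time, basis = NULL,
                                  num_basis = 10) {
  t_std <- (to_decimal_date(dates) - std_time$center) / std_time$scale
  if (is.null(basis)) basis <- spline_basis(t_std, num_basis = num_basis)
  Z <- spline_basis_eval(basis, t_std)
  new_design(month_design(dates), includes_intercept = TRUE,
             spline = list(basis = basis, Z = Z))
}
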