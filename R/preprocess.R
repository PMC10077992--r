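#' Raw hourly PNSD panel
#'
#' Container for an hourly particle number size distribution panel before any
#' data reduction: rows are size bins, columns are time stamps. Missing cells
#' (instrument downtime) are carried in a logical mask; `NA` in `values` is
#' converted to a masked cell.
#'
#' @param times `POSIXct` vector of hourly time stamps, strictly increasing,
#'   no duplicates.
#' @param bin_labels numeric vector of size-bin midpoints in nm, strictly
#'   increasing.
#' @param values numeric matrix, rows = bins, columns = times; nonnegative
#'   wherever observed (particles/cm3).
#' @param missing_mask optional logical matrix of the same shape; `TRUE` marks
#'   a missing cell. Defaults to `is.na(values)`.
#' @return An object of class `raw_pnsd`.
#' @export
raw_pnsd <- function(times, bin_labels, values, missing_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- missing_mask | is.na(values)
  stopifnot(length(bin_labels) == nrow(values), length(times) == ncol(values))
  if (anyDuplicated(times)) stop("duplicate time stamps")
  if (is.unsorted(bin_labels, strictly = TRUE))
    stop("bin_labels must be strictly increasing")
  if (any(values[!missing_mask] < 0))
    stop("negative concentrations in observed cells")
  values[missing_mask] <- NA_real_
  structure(list(times = times, bin_labels = as.numeric(bin_labels),
                 values = values, missing_mask = missing_mask),
            class = "raw_pnsd")
}

#' @export
print.raw_pnsd <- function(x, ...) {
  cat(sprintf("<raw_pnsd> %d bins (%.1f-%.1f nm) x %d hourly steps, %.1f%% missing\n",
              nrow(x$values), min(x$bin_labels), max(x$bin_labels),
              ncol(x$values), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' Wind covariate series
#'
#' Wind speed (m/s) and wind direction (degrees clockwise from north, in
#' `[0, 360)`) aligned to a time axis. `NA` entries are allowed until
#' [impute_covariates_mean()] is applied.
#'
#' @param ws numeric vector of wind speeds (m/s, nonnegative).
#' @param wd numeric vector of wind directions (degrees in `[0, 360)`).
#' @param times optional time stamps aligned with `ws`/`wd`.
#' @return An object of class `wind_series`.
#' @export
wind_series <- function(ws, wd, times = NULL) {
  stopifnot(length(ws) == length(wd))
  if (!is.null(times)) stopifnot(length(times) == length(ws))
  if (any(ws < 0, na.rm = TRUE)) stop("wind speed must be nonnegative")
  if (any(wd < 0 | wd >= 360, na.rm = TRUE))
    stop("wind direction must lie in [0, 360)")
  structure(list(ws = as.numeric(ws), wd = as.numeric(wd), times = times),
            class = "wind_series")
}

#' @export
print.wind_series <- function(x, ...) {
  cat(sprintf("<wind_series> T=%d, ws %.1f-%.1f m/s, %d missing ws, %d missing wd\n",
              length(x$ws), min(x$ws, na.rm = TRUE), max(x$ws, na.rm = TRUE),
              sum(is.na(x$ws)), sum(is.na(x$wd))))
  invisible(x)
}

# Pearson correlation with a convention for degenerate (constant) series:
# two constant series are treated as perfectly correlated (they carry the
# same, i.e. no, information and should aggregate); one constant against a
# varying series is treated as uncorrelated.
.safe_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 && sy == 0) return(1)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

#' Plan the correlation-driven aggregation of size bins
#'
#' Greedy left-to-right partition of consecutive size bins: a group anchored
#' at bin `p` is extended to bin `p+q` as long as the Pearson correlation
#' between the anchor series and the candidate series (over jointly observed
#' times, raw concentrations) is at least `tau`; the first candidate falling
#' below `tau` starts a new group.
#'
#' @param raw a [raw_pnsd()] panel with at least two bins.
#' @param tau correlation threshold in `[0, 1]` (values above 1 yield the
#'   identity, all-singleton plan).
#' @return An `aggregation_plan`: list with `axis = "bin"`, `groups` (list of
#'   integer index vectors), `tau`, and `correlations` (per group, the
#'   anchor-to-member correlations that justified each merge).
#' @export
plan_bin_aggregation <- function(raw, tau) {
  stopifnot(inherits(raw, "raw_pnsd"))
  P <- nrow(raw$values)
  if (P < 2L) stop("need at least 2 bins to plan aggregation")
  groups <- list(); cors <- list()
  p <- 1L
  while (p <= P) {
    grp <- p; gc_ <- numeric(0)
    anchor <- raw$values[p, ]
    q <- p + 1L
    while (q <= P) {
      cand <- raw$values[q, ]
      n_joint <- sum(!is.na(anchor) & !is.na(cand))
      if (n_joint < 2L)
        stop(sprintf("bins %g nm and %g nm share fewer than 2 observed time points",
                     raw$bin_labels[p], raw$bin_labels[q]))
      r <- .safe_cor(anchor, cand)
      if (is.na(r) || r < tau) break
      grp <- c(grp, q); gc_ <- c(gc_, r)
      q <- q + 1L
    }
    groups[[length(groups) + 1L]] <- grp
    cors[[length(cors) + 1L]] <- gc_
    p <- q
  }
  structure(list(axis = "bin", groups = groups, tau = tau,
                 correlations = cors),
            class = "aggregation_plan")
}

#' @export
print.aggregation_plan <- function(x, ...) {
  cat(sprintf("<aggregation_plan> axis=%s, tau=%g: %d groups of sizes %s\n",
              x$axis, x$tau, length(x$groups),
              paste(lengths(x$groups), collapse = ",")))
  invisible(x)
}

.check_plan_covers <- function(plan, n) {
  idx <- unlist(plan$groups)
  if (!identical(sort(idx), seq_len(n)) || any(diff(idx) != 1L))
    stop("plan does not form a contiguous partition of all indices")
}

#' Apply a size-bin aggregation plan
#'
#' Within each group, concentrations are summed per time step so the new bin
#' carries the total particle count of its members (total count is conserved).
#' The representative label of a merged bin is the geometric mean of the
#' member midpoints (sizes are log-spaced); the member endpoints are retained
#' in `bin_lo`/`bin_hi`. A merged cell is missing if any member is missing
#' (with instrument-downtime missingness this is column-wise and degenerate).
#'
#' @param raw a [raw_pnsd()] panel.
#' @param plan a bin `aggregation_plan` covering the bins of `raw`.
#' @return A [raw_pnsd()] with one row per group and attributes `bin_lo`,
#'   `bin_hi` giving the endpoints (nm) of each aggregated bin.
#' @export
apply_bin_aggregation <- function(raw, plan) {
  stopifnot(inherits(raw, "raw_pnsd"), identical(plan$axis, "bin"))
  .check_plan_covers(plan, nrow(raw$values))
  G <- length(plan$groups)
  vals <- matrix(NA_real_, G, ncol(raw$values))
  miss <- matrix(FALSE, G, ncol(raw$values))
  lab <- lo <- hi <- numeric(G)
  for (g in seq_len(G)) {
    idx <- plan$groups[[g]]
    sub <- raw$values[idx, , drop = FALSE]
    miss[g, ] <- apply(raw$missing_mask[idx, , drop = FALSE], 2, any)
    vals[g, ] <- colSums(sub)
    lab[g] <- exp(mean(log(raw$bin_labels[idx])))
    lo[g] <- raw$bin_labels[idx[1L]]
    hi[g] <- raw$bin_labels[idx[length(idx)]]
  }
  vals[miss] <- NA_real_
  out <- raw_pnsd(raw$times, lab, vals, miss)
  attr(out, "bin_lo") <- lo
  attr(out, "bin_hi") <- hi
  out
}

# Rearranges an hourly panel into a day x 24-hour x bin array; absent time
# stamps become missing cells.
.day_hour_array <- function(raw) {
  day <- as.Date(raw$times, tz = "UTC")
  hour <- as.integer(format(raw$times, "%H", tz = "UTC"))
  days <- sort(unique(day))
  P <- nrow(raw$values)
  arr <- array(NA_real_, c(length(days), 24L, P))
  di <- match(day, days)
  for (p in seq_len(P))
    arr[cbind(di, hour + 1L, p)] <- raw$values[p, ]
  list(arr = arr, days = days)
}

#' Plan the correlation-driven aggregation of hours of day
#'
#' For each size bin, the series of a given hour of day across days is
#' correlated with the series of later hours; consecutive hours are merged
#' greedily (anchored to the group's first hour) while the merge criterion is
#' at least `tau`. The criterion pools the per-bin correlations either as the
#' minimum over bins (`method = "min"`, conservative default: every bin must
#' co-move) or as a single pooled correlation over all bins' stacked day
#' pairs (`method = "pooled"`). One partition of the 24 hours, shared by all
#' bins, is returned.
#'
#' @param raw a [raw_pnsd()] panel with hourly time stamps spanning >= 2 days.
#' @param tau correlation threshold.
#' @param method `"min"` or `"pooled"` (see above).
#' @return An `aggregation_plan` with `axis = "hour"` and `groups` a partition
#'   of hours `0..23` (stored 1-based as indices `1..24`).
#' @export
plan_hour_aggregation <- function(raw, tau, method = c("min", "pooled")) {
  stopifnot(inherits(raw, "raw_pnsd"))
  method <- match.arg(method)
  dh <- .day_hour_array(raw)
  if (length(dh$days) < 2L) stop("need at least 2 days of data")
  arr <- dh$arr
  P <- dim(arr)[3]
  crit <- function(a, b) {
    if (method == "min") {
      r <- vapply(seq_len(P), function(p) .safe_cor(arr[, a, p], arr[, b, p]),
                  numeric(1))
      if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE)
    } else {
      .safe_cor(as.vector(arr[, a, ]), as.vector(arr[, b, ]))
    }
  }
  groups <- list(); cors <- list()
  a <- 1L
  while (a <= 24L) {
    grp <- a; gc_ <- numeric(0)
    b <- a + 1L
    while (b <= 24L) {
      r <- crit(a, b)
      if (is.na(r) || r < tau) break
      grp <- c(grp, b); gc_ <- c(gc_, r)
      b <- b + 1L
    }
    groups[[length(groups) + 1L]] <- grp
    cors[[length(cors) + 1L]] <- gc_
    a <- b
  }
  structure(list(axis = "hour", groups = groups, tau = tau,
                 correlations = cors, method = method),
            class = "aggregation_plan")
}

#' Apply an hour aggregation plan, producing the model-ready panel
#'
#' Within each (day, hour-group), concentrations are averaged over the
#' non-missing member hours; the aggregated time step is missing only when
#' all member hours are missing. The result is the reduced panel the model
#' consumes, with each time step labelled by its within-day block.
#'
#' @param raw a [raw_pnsd()] hourly panel.
#' @param plan an hour `aggregation_plan` covering hours 0-23.
#' @return A `pnsd_matrix`: list with `times` (block start stamps), `day`,
#'   `block` (within-day block id per time step), `block_labels` (e.g.
#'   `"0-6h"`), `bin_labels`/`bin_lo`/`bin_hi`, `values` (P x T), and
#'   `missing_mask`.
#' @export
apply_hour_aggregation <- function(raw, plan) {
  stopifnot(inherits(raw, "raw_pnsd"), identical(plan$axis, "hour"))
  .check_plan_covers(plan, 24L)
  dh <- .day_hour_array(raw)
  arr <- dh$arr; days <- dh$days
  P <- dim(arr)[3]; D <- length(days); G <- length(plan$groups)
  Tt <- D * G
  vals <- matrix(NA_real_, P, Tt)
  day_out <- rep(days, each = G)
  block_out <- rep(seq_len(G), times = D)
  start_hour <- vapply(plan$groups, function(g) g[1L] - 1L, integer(1))
  end_hour <- vapply(plan$groups, function(g) g[length(g)], integer(1))
  block_labels <- sprintf("%d-%dh", start_hour, end_hour)
  for (g in seq_len(G)) {
    sub <- arr[, plan$groups[[g]], , drop = FALSE]          # D x |g| x P
    m <- apply(sub, c(1, 3), function(v) mean(v, na.rm = TRUE))  # D x P
    m[is.nan(m)] <- NA_real_
    vals[, (seq_len(D) - 1L) * G + g] <- t(m)
  }
  times <- as.POSIXct(paste0(day_out, " ", sprintf("%02d", start_hour[block_out]),
                             ":00:00"), tz = "UTC")
  bin_lo <- attr(raw, "bin_lo"); bin_hi <- attr(raw, "bin_hi")
  if (is.null(bin_lo)) bin_lo <- raw$bin_labels
  if (is.null(bin_hi)) bin_hi <- raw$bin_labels
  pnsd_matrix(times = times, bin_labels = raw$bin_labels, values = vals,
              block = block_out, block_labels = block_labels,
              day = day_out, bin_lo = bin_lo, bin_hi = bin_hi)
}

#' Model-ready PNSD panel
#'
#' The reduced concentration panel consumed by the sampler: P aggregated size
#' bins by T reduced time steps (day within-day block), with a missingness
#' mask. After [replace_zeros()] all observed values are strictly positive.
#'
#' @param times `POSIXct` block-start stamps.
#' @param bin_labels representative sizes (nm) of the aggregated bins.
#' @param values numeric P x T matrix.
#' @param block integer within-day block id per time step.
#' @param block_labels character labels of the within-day blocks.
#' @param day `Date` per time step (defaults from `times`).
#' @param bin_lo,bin_hi endpoints (nm) of each aggregated bin.
#' @param missing_mask optional logical P x T mask; defaults to `is.na(values)`.
#' @return An object of class `pnsd_matrix`.
#' @export
pnsd_matrix <- function(times, bin_labels, values, block,
                        block_labels = NULL, day = NULL,
                        bin_lo = bin_labels, bin_hi = bin_labels,
                        missing_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- missing_mask | is.na(values)
  values[missing_mask] <- NA_real_
  if (is.null(day)) day <- as.Date(times, tz = "UTC")
  if (is.null(block_labels)) block_labels <- as.character(sort(unique(block)))
  stopifnot(length(bin_labels) == nrow(values),
            length(times) == ncol(values),
            length(block) == ncol(values))
  structure(list(times = times, day = day, block = as.integer(block),
                 block_labels = block_labels,
                 bin_labels = as.numeric(bin_labels),
                 bin_lo = as.numeric(bin_lo), bin_hi = as.numeric(bin_hi),
                 values = values, missing_mask = missing_mask),
            class = "pnsd_matrix")
}

#' @export
print.pnsd_matrix <- function(x, ...) {
  cat(sprintf("<pnsd_matrix> %d bins x %d time steps (%d within-day blocks), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), length(x$block_labels),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' Replace exact zeros by half the bin minimum
#'
#' Zero concentrations are artifacts of values below the instrument detection
#' threshold; each exact zero in a bin is replaced by half of the minimum
#' non-zero observed value of that bin. Non-zero entries are untouched.
#'
#' @param m a `pnsd_matrix` (or `raw_pnsd`).
#' @return The input with zeros replaced; attribute `n_replaced` carries the
#'   replacement count, `replaced_per_bin` the per-bin counts.
#' @export
replace_zeros <- function(m) {
  v <- m$values
  nrep <- integer(nrow(v))
  for (p in seq_len(nrow(v))) {
    row <- v[p, ]
    nz <- row[!is.na(row) & row > 0]
    zero <- which(!is.na(row) & row == 0)
    if (length(nz) == 0L)
      stop(sprintf("bin %g has no non-zero observed value", m$bin_labels[p]))
    if (length(zero)) {
      v[p, zero] <- min(nz) / 2
      nrep[p] <- length(zero)
    }
  }
  m$values <- v
  attr(m, "n_replaced") <- sum(nrep)
  attr(m, "replaced_per_bin") <- nrep
  m
}

#' Mean-impute missing wind covariates
#'
#' Missing wind speeds are replaced by the arithmetic mean of the observed
#' speeds; missing wind directions by the arithmetic mean of the observed
#' direction values in degrees (the plain, non-circular convention; set
#' `circular = TRUE` for the vector-mean alternative). Intended for small
#' missing fractions; warns above 5%.
#'
#' @param w a [wind_series()].
#' @param circular use the circular (vector) mean for direction.
#' @return The completed `wind_series`, with attribute `n_imputed` =
#'   `c(ws = ..., wd = ...)`.
#' @export
impute_covariates_mean <- function(w, circular = FALSE) {
  stopifnot(inherits(w, "wind_series"))
  na_ws <- is.na(w$ws); na_wd <- is.na(w$wd)
  if (all(na_ws) || all(na_wd)) stop("covariate entirely missing")
  if (mean(na_ws) > 0.05 || mean(na_wd) > 0.05)
    warning("more than 5% of wind covariates missing; mean imputation may be inadequate")
  w$ws[na_ws] <- mean(w$ws[!na_ws])
  if (circular) {
    rad <- w$wd[!na_wd] * pi / 180
    ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
    w$wd[na_wd] <- ang %% 360
  } else {
    w$wd[na_wd] <- mean(w$wd[!na_wd])
  }
  attr(w, "n_imputed") <- c(ws = sum(na_ws), wd = sum(na_wd))
  w
}

#' Aggregate an hourly wind series onto the reduced time axis
#'
#' Averages wind over each (day, hour-block) so the covariates sit on the same
#' reduced time steps as the aggregated PNSD panel: arithmetic mean for speed,
#' vector (circular) mean for direction.
#'
#' @param w hourly [wind_series()] with `times` set.
#' @param plan the hour `aggregation_plan` used for the panel.
#' @param target a `pnsd_matrix` defining the output time axis.
#' @return A `wind_series` aligned to `target$times`.
#' @export
aggregate_wind <- function(w, plan, target) {
  stopifnot(inherits(w, "wind_series"), !is.null(w$times),
            identical(plan$axis, "hour"), inherits(target, "pnsd_matrix"))
  day <- as.Date(w$times, tz = "UTC")
  hour <- as.integer(format(w$times, "%H", tz = "UTC"))
  grp <- integer(24L)
  for (g in seq_along(plan$groups)) grp[plan$groups[[g]]] <- g
  key <- paste(day, grp[hour + 1L])
  tkey <- paste(target$day, target$block)
  ws <- tapply(w$ws, key, mean, na.rm = TRUE)
  sinm <- tapply(sin(w$wd * pi / 180), key, mean, na.rm = TRUE)
  cosm <- tapply(cos(w$wd * pi / 180), key, mean, na.rm = TRUE)
  wd <- (atan2(sinm, cosm) * 180 / pi) %% 360
  ws_out <- as.numeric(ws[tkey]); wd_out <- as.numeric(wd[tkey])
  ws_out[is.nan(ws_out)] <- NA_real_
  wd_out[is.nan(wd_out)] <- NA_real_
  wind_series(ws_out, wd_out, times = target$times)
}

#' Bookkeeping of a data reduction
#'
#' Cell counts before and after aggregation and the implied percentage
#' reduction, from panel dimensions (time steps x bins).
#'
#' @param n_time_pre,n_bins_pre dimensions before reduction.
#' @param n_time_post,n_bins_post dimensions after reduction.
#' @return list with `cells_pre`, `cells_post`, `percent_reduction`
#'   (in percent, rounded to 0.1).
#' @export
reduction_summary <- function(n_time_pre, n_bins_pre, n_time_post, n_bins_post) {
  pre <- as.numeric(n_time_pre) * as.numeric(n_bins_pre)
  post <- as.numeric(n_time_post) * as.numeric(n_bins_post)
  list(cells_pre = pre, cells_post = post,
       percent_reduction = round(100 * (1 - post / pre), 1))
}
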