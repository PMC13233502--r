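#' Digitized Kaplan-Meier input
#'
#' Container for digitized survival-curve coordinates plus the published
#' number-at-risk table, the inputs to [reconstruct_ipd()].
#'
#' @param points Data frame with columns `time` (months, strictly
#'   increasing) and `surv` (non-increasing, starting at <= 1).
#' @param risk_table Data frame with columns `time` (months, strictly
#'   increasing) and `n_risk` (non-increasing positive integers).
#' @param total_events Optional total number of events reported for the
#'   curve; when given, reconstruction adjusts the tail allocation toward
#'   it.
#' @return An object of class `km_digitized`.
#' @export
km_digitized <- function(points, risk_table, total_events = NULL) {
  stopifnot(all(c("time", "surv") %in% names(points)),
            all(c("time", "n_risk") %in% names(risk_table)))
  points <- points[order(points$time), c("time", "surv")]
  risk_table <- risk_table[order(risk_table$time), c("time", "n_risk")]
  if (any(diff(points$time) <= 0)) stop("digitized times must be strictly increasing")
  if (any(diff(risk_table$time) <= 0)) stop("risk-table times must be strictly increasing")
  if (any(diff(points$surv) > 1e-12)) stop("survival fractions must be non-increasing")
  if (points$surv[1] > 1 + 1e-12) stop("survival fractions must start at <= 1")
  if (any(diff(risk_table$n_risk) > 0)) stop("at-risk counts must be non-increasing")
  if (any(risk_table$n_risk < 0)) stop("at-risk counts must be non-negative")
  structure(list(points = points, risk_table = risk_table,
                 total_events = total_events), class = "km_digitized")
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Implements the iterative reconstruction algorithm of Guyot and
#' colleagues: within each interval between consecutive number-at-risk
#' times, censorings are assumed uniformly spread and their count adjusted
#' until the at-risk count implied by inverting the product-limit steps
#' matches the published figure at the start of the next interval. Event
#' counts per digitized step follow from the KM identity
#' `S(t_j) = S(t_last_event) * (1 - d_j / n_j)`. After the last at-risk
#' time, events are read off the remaining steps and surviving subjects
#' are censored at the end of follow-up; when `total_events` is supplied,
#' censoring in the tail interval is increased until the event total does
#' not exceed it.
#'
#' @param km A [km_digitized()] object with at least two risk-table rows.
#' @return Data frame with columns `time` and `event`, one row per subject;
#'   the number of rows equals the initial at-risk count.
#' @references Guyot P, Ades AE, Ouwens MJNM, Welton NJ. Enhanced secondary
#'   analysis of survival data: reconstructing the data from published
#'   Kaplan-Meier survival curves. BMC Med Res Methodol. 2012;12:9.
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "km_digitized"))
  rt <- km$risk_table
  if (nrow(rt) < 2) stop("need at least two risk-table entries")

  pts <- km$points
  if (pts$time[1] > rt$time[1])
    pts <- rbind(data.frame(time = rt$time[1], surv = 1), pts)
  t.S <- pts$time
  S <- pmin(pts$surv, 1)
  n.click <- length(t.S)
  n.int <- nrow(rt)

  d <- numeric(n.click)             # events tied to each click
  KM.hat <- rep(1, n.click)         # reconstructed product-limit at clicks
  cen.times <- numeric(0)           # explicit censoring times

  # invert the KM steps of one interval given a censor count spread
  # uniformly over [t.start, t.end); returns the implied end state
  walk <- function(J, n.start, KM.last, n.cen, t.start, t.end) {
    cen.t <- if (n.cen > 0)
      t.start + (seq_len(n.cen) - 0.5) / n.cen * (t.end - t.start)
    else numeric(0)
    n <- n.start
    km.last <- KM.last
    d.loc <- km.loc <- numeric(length(J))
    t.prev <- t.start
    for (idx in seq_along(J)) {
      j <- J[idx]
      n <- max(0, n - sum(cen.t >= t.prev & cen.t < t.S[j]))  # censors before click
      ev <- if (n > 0 && km.last > 0) round(n * (1 - S[j] / km.last)) else 0
      ev <- min(max(ev, 0), n)
      km.loc[idx] <- if (n > 0) km.last * (1 - ev / n) else km.last
      if (ev > 0) km.last <- km.loc[idx]
      d.loc[idx] <- ev
      n <- n - ev
      t.prev <- t.S[j]
    }
    n <- max(0, n - sum(cen.t >= t.prev))  # censors after the last click
    list(d = d.loc, km = km.loc, cen.t = cen.t, n.end = n, KM.last = km.last)
  }

  n.cur <- rt$n_risk[1]
  KM.last <- 1
  for (i in seq_len(n.int - 1)) {
    t0 <- rt$time[i]; t1 <- rt$time[i + 1]
    J <- which(t.S >= t0 & t.S < t1)
    target <- rt$n_risk[i + 1]
    if (!length(J)) {
      # no visible steps: the whole decline is censoring, spread uniformly
      n.cen <- n.cur - target
      if (n.cen < 0)
        stop("inconsistent risk table in interval ", i,
             ": implied negative censoring")
      if (n.cen > 0)
        cen.times <- c(cen.times,
                       t0 + (seq_len(n.cen) - 0.5) / n.cen * (t1 - t0))
      n.cur <- target
      next
    }
    s.start <- S[min(J)]
    s.end <- S[max(J)]
    guess <- if (s.start > 0)
      round(n.cur * s.end / s.start) - target else n.cur - target
    n.cen <- max(0, guess)
    prev <- -1L
    repeat {
      st <- walk(J, n.cur, KM.last, n.cen, t0, t1)
      diff.n <- st$n.end - target
      if (diff.n == 0) break
      new.cen <- max(0, n.cen + diff.n)
      if (new.cen == n.cen || new.cen == prev) break  # rounding cycle
      prev <- n.cen
      n.cen <- new.cen
    }
    # the steps alone can consume more subjects than the risk table admits;
    # a couple of subjects is rounding drift, more means the inputs are
    # structurally inconsistent
    short <- target - st$n.end
    if (short > max(2, ceiling(0.05 * n.cur)))
      stop("inconsistent risk table in interval ", i,
           ": implied negative censoring")
    d[J] <- st$d; KM.hat[J] <- st$km
    cen.times <- c(cen.times, st$cen.t)
    # any residual surplus after a rounding cycle is censored at interval end
    if (st$n.end > target)
      cen.times <- c(cen.times, rep(t1 - 1e-9, st$n.end - target))
    n.cur <- min(target, st$n.end)
    KM.last <- st$KM.last
  }

  # tail: clicks at/after the last risk time
  t0 <- rt$time[n.int]
  J <- which(t.S >= t0)
  t.max <- max(t.S[n.click], t0)
  n.cen.tail <- 0
  repeat {
    st <- walk(J, n.cur, KM.last, n.cen.tail, t0, t.max + 1e-9)
    if (is.null(km$total_events)) break
    excess <- (sum(d[setdiff(seq_len(n.click), J)]) + sum(st$d)) -
      km$total_events
    if (excess <= 0 || n.cen.tail >= n.cur) break
    n.cen.tail <- min(n.cur, n.cen.tail + max(1, excess))
  }
  d[J] <- st$d; KM.hat[J] <- st$km
  cen.times <- c(cen.times, st$cen.t)
  leftover <- max(0, st$n.end)

  # reconcile integer-rounding drift against the initial cohort size:
  # surplus censors are dropped from the tail, missing subjects are
  # censored at the end of follow-up; gross mismatch is an input error
  n0 <- rt$n_risk[1]
  excess <- (sum(d) + length(cen.times) + leftover) - n0
  if (abs(excess) > max(3, ceiling(0.01 * n0)))
    stop("reconstruction lost subjects: got ", n0 + excess, ", expected ", n0)
  if (excess > 0) {
    drop <- min(excess, leftover)
    leftover <- leftover - drop
    excess <- excess - drop
    if (excess > 0)
      cen.times <- cen.times[seq_len(length(cen.times) - excess)]
  } else if (excess < 0) {
    leftover <- leftover - excess
  }
  out <- data.frame(
    time = c(rep(t.S, times = d), cen.times, rep(t.max, leftover)),
    event = c(rep(1, sum(d)), rep(0, length(cen.times) + leftover)))
  out[order(out$time), , drop = FALSE]
}

#' Product-limit (Kaplan-Meier) estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' data frame, used for round-trip validation of the reconstruction.
#'
#' @param data Data frame with `time` and `event` columns.
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `surv`,
#'   starting at `(0, n, 0, 1)`.
#' @export
km_curve <- function(data) {
  check_ipd(data)
  if (nrow(data) == 0) stop("empty dataset")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  data.frame(time = c(0, fit$time), n_risk = c(nrow(data), fit$n.risk),
             n_event = c(0, fit$n.event), surv = c(1, fit$surv))
}

# step-function evaluation of a km_curve data frame
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  km$surv[pmax(idx, 1)]
}
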