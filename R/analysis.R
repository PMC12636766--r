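#' Steady-state active-target fraction
#'
#' Mean over post-burn-in trace records of (active target count) / (total
#' target count).
#'
#' @param x A `sim_result` or an activity trace tibble with columns `sweep`,
#'   `component`, `state`, `count` (in which case `network` must be given).
#' @param burn_in Sweeps to discard; defaults to the config's `burn_in` for a
#'   `sim_result`, else 0.
#' @param network The `network_spec` naming the target and its active state
#'   (taken from the result when `x` is a `sim_result`).
#' @return `f_A` in `[0, 1]`.
#' @export
steady_state_activity <- function(x, burn_in = NULL, network = NULL) {
  if (inherits(x, "sim_result")) {
    network <- network %||% x$config$network
    burn_in <- burn_in %||% x$config$burn_in
    trace <- x$trace
  } else {
    trace <- x
    burn_in <- burn_in %||% 0L
    if (is.null(network)) stop("supply `network` when passing a raw trace")
  }
  tgt <- trace[trace$component == network$target, , drop = FALSE]
  keep <- tgt$sweep >= burn_in
  tgt <- tgt[keep, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("no trace records at or after burn_in")
  totals <- tapply(tgt$count, tgt$sweep, sum)
  act <- tgt[tgt$state == network$active_state, , drop = FALSE]
  active <- tapply(act$count, act$sweep, sum)
  mean(active / totals)
}

#' Fit a generalized logistic (tanh) activity curve
#'
#' Fits `f_A(tau) = (R - L)/2 * tanh((tau - tau0) / (2 * dtau)) + (R + L)/2`
#' by bounded nonlinear least squares (Levenberg-Marquardt). `L` and `R` are
#' the left/right asymptotes, `dtau` the growth width (smaller = sharper
#' temperature sensitivity), and `tau0` the inflection point — the
#' temperature of steepest activity change. Starting values come from the
#' data (edge means for the asymptotes, the steepest finite-difference
#' segment for `tau0`). Confidence intervals are Wald intervals from the fit
#' covariance.
#'
#' @param tau Numeric vector of rescaled temperatures (replicates allowed).
#' @param f_A Activity fractions, same length as `tau`.
#' @param conf_level Confidence level for the parameter intervals.
#' @param bounded Constrain the asymptotes to `[0, 1]` (appropriate for
#'   activity fractions).
#' @return A `logistic_fit`: list with `L_asym`, `R_asym`, `delta_tau`,
#'   `tau0`, `ci` (parameter interval matrix), `se`, `converged`,
#'   `unidentifiable`, `residual_norm`, `n`, and the underlying `fit` object
#'   (or `NULL`). Non-convergence and flat data are flagged, not thrown.
#' @export
fit_logistic <- function(tau, f_A, conf_level = 0.95, bounded = TRUE) {
  stopifnot(length(tau) == length(f_A), is.numeric(tau), is.numeric(f_A))
  if (length(unique(tau)) < 4L) {
    stop("need >= 4 distinct tau values spanning the rise")
  }
  mt <- tapply(f_A, tau, mean)
  tt <- as.numeric(names(mt))
  o <- order(tt)
  tt <- tt[o]
  mt <- as.numeric(mt)[o]
  flat <- diff(range(mt)) < 1e-9
  out <- list(L_asym = mt[1], R_asym = mt[length(mt)], delta_tau = NA_real_,
              tau0 = NA_real_, ci = NULL, se = NULL, converged = FALSE,
              unidentifiable = FALSE, residual_norm = NA_real_,
              n = length(tau), fit = NULL)
  class(out) <- "logistic_fit"
  if (flat) {
    out$L_asym <- out$R_asym <- mean(mt)
    out$unidentifiable <- TRUE
    return(out)
  }
  lo0 <- mt[1]
  hi0 <- mt[length(mt)]
  slopes <- diff(mt) / diff(tt)
  i <- which.max(abs(slopes))
  tau00 <- (tt[i] + tt[i + 1]) / 2
  dt0 <- abs((hi0 - lo0) / (4 * slopes[i]))
  dt0 <- max(min(dt0, diff(range(tt))), diff(range(tt)) / 200)
  span <- diff(range(tt))
  lower <- c(lo = if (bounded) 0 else -Inf, hi = if (bounded) 0 else -Inf,
             dt = 1e-6, tau0 = min(tt) - span)
  upper <- c(lo = if (bounded) 1 else Inf, hi = if (bounded) 1 else Inf,
             dt = 10 * span, tau0 = max(tt) + span)
  dat <- data.frame(tau = tau, f = f_A)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ (hi - lo) / 2 * tanh((tau - tau0) / (2 * dt)) + (hi + lo) / 2,
      data = dat,
      start = list(lo = min(max(lo0, lower["lo"]), upper["lo"]),
                   hi = min(max(hi0, lower["hi"]), upper["hi"]),
                   dt = dt0, tau0 = tau00),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  tq <- qt(1 - (1 - conf_level) / 2, df = max(length(tau) - 4L, 1L))
  ci <- cbind(lower = cf - tq * se, upper = cf + tq * se)
  rownames(ci) <- c("L_asym", "R_asym", "delta_tau", "tau0")
  out$L_asym <- unname(cf["lo"])
  out$R_asym <- unname(cf["hi"])
  out$delta_tau <- unname(cf["dt"])
  out$tau0 <- unname(cf["tau0"])
  out$ci <- ci
  out$se <- stats::setNames(se, rownames(ci))
  out$converged <- fit$convInfo$isConv %||% TRUE
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$fit <- fit
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$unidentifiable) {
    cat(sprintf(
      "<logistic_fit> flat data: asymptotes %.4f, growth width unidentifiable\n",
      x$L_asym))
    return(invisible(x))
  }
  cat(sprintf(
    "<logistic_fit> L=%.4f R=%.4f delta_tau=%.4f tau0=%.4f (converged: %s)\n",
    x$L_asym, x$R_asym, x$delta_tau, x$tau0, x$converged))
  if (!is.null(x$ci)) {
    cat(sprintf("  tau0 CI [%.4f, %.4f], delta_tau CI [%.4f, %.4f]\n",
                x$ci["tau0", 1], x$ci["tau0", 2],
                x$ci["delta_tau", 1], x$ci["delta_tau", 2]))
  }
  invisible(x)
}

#' Predicted activity from a logistic fit
#'
#' @param object A `logistic_fit`.
#' @param tau Temperatures at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of fitted activities.
#' @export
predict.logistic_fit <- function(object, tau, ...) {
  if (object$unidentifiable) return(rep(object$L_asym, length(tau)))
  (object$R_asym - object$L_asym) / 2 *
    tanh((tau - object$tau0) / (2 * object$delta_tau)) +
    (object$R_asym + object$L_asym) / 2
}

#' Radially averaged cross-correlation between two component types
#'
#' Builds indicator occupancy fields (1 on every footprint site of an
#' inclusion of the given type) for each snapshot and computes the
#' normalized cross-correlation
#' `g(r) = <rho_A(x) rho_B(x + r)> / (<rho_A> <rho_B>)`
#' over periodic displacements, averaged over directions into radial bins
#' and over snapshots. A value of 1 means no association; > 1 means the
#' types co-locate at that distance.
#'
#' @param x A `sim_result` with snapshots, or a list of `lattice_state`
#'   snapshots.
#' @param type_a,type_b Component names.
#' @param max_radius Largest radial distance (defaults to `L / 2`).
#' @param bin_width Radial bin width in lattice units.
#' @return A `correlation_profile` tibble: `r` (bin centre), `correlation`,
#'   `pair`, `n_snapshots`.
#' @export
cross_correlation <- function(x, type_a, type_b, max_radius = NULL,
                              bin_width = 1) {
  snaps <- if (inherits(x, "sim_result")) x$snapshots else x
  if (length(snaps) == 0L) stop("no snapshots available")
  L <- snaps[[1]]$L
  max_radius <- max_radius %||% (L / 2)
  # periodic displacement distances, shared across snapshots
  d1 <- pmin(0:(L - 1), L - (0:(L - 1)))
  dist <- sqrt(outer(d1^2, d1^2, "+"))
  bins <- floor(dist / bin_width + 0.5)  # bin k covers r in [k-.5, k+.5)*w
  keep <- dist <= max_radius
  num <- 0
  den <- 0
  used <- 0L
  for (sn in snaps) {
    ids_a <- sn$inclusions$id[sn$inclusions$component == type_a]
    ids_b <- sn$inclusions$id[sn$inclusions$component == type_b]
    if (length(ids_a) == 0L || length(ids_b) == 0L) next
    A <- matrix(as.numeric(sn$occupancy %in% ids_a), L, L)
    B <- matrix(as.numeric(sn$occupancy %in% ids_b), L, L)
    # periodic cross-correlation sum_x A(x) B(x + r) via FFT
    S <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) /
      (L * L)
    g <- (S / (L * L)) / (mean(A) * mean(B))
    num <- num + tapply(g[keep], bins[keep], sum)
    den <- den + tapply(rep(1, sum(keep)), bins[keep], sum)
    used <- used + 1L
  }
  if (used == 0L) stop("types '", type_a, "'/'", type_b,
                       "' absent from all snapshots")
  structure(
    tibble::tibble(
      r = as.numeric(names(num)) * bin_width,
      correlation = as.numeric(num / den),
      pair = paste(type_a, type_b, sep = ":"),
      n_snapshots = used
    ),
    class = c("correlation_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Label connected clusters of the ordered phase
#'
#' Four-connected clusters (periodic boundaries) of the mask formed by
#' ordered lipids (`spin == +1`) plus sites of inclusions whose current
#' boundary preference is `+1`.
#'
#' @param state A `lattice_state`.
#' @return Integer `L x L` matrix of cluster labels (0 outside the mask).
#' @keywords internal
label_ordered_clusters <- function(state) {
  L <- state$L
  mask <- state$spins == 1L
  if (nrow(state$inclusions) > 0L) {
    for (i in seq_len(nrow(state$inclusions))) {
      cmp <- state$network$components[[state$inclusions$component[i]]]
      b <- cmp$states[[state$inclusions$state[i]]]
      if (b == 1L) mask[state$occupancy == state$inclusions$id[i]] <- TRUE
    }
  }
  lab <- matrix(0L, L, L)
  nxt <- 0L
  idx <- which(mask)
  for (s0 in idx) {
    if (lab[s0] != 0L) next
    nxt <- nxt + 1L
    queue <- s0
    lab[s0] <- nxt
    while (length(queue)) {
      s <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      x <- (s - 1L) %% L
      y <- (s - 1L) %/% L
      nb <- c((x + 1L) %% L + y * L, (x - 1L) %% L + y * L,
              x + ((y + 1L) %% L) * L, x + ((y - 1L) %% L) * L) + 1L
      for (t in nb) {
        if (mask[t] && lab[t] == 0L) {
          lab[t] <- nxt
          queue <- c(queue, t)
        }
      }
    }
  }
  lab
}

#' Flag high-activity outlier replicates
#'
#' A replicate is flagged when its activity exceeds the replicate median by
#' more than `k` median absolute deviations — the distributional signature
#' of pocketing runs.
#'
#' @param f_A Numeric vector of per-replicate steady-state activities.
#' @param k MAD multiplier.
#' @return Logical vector, `TRUE` for flagged replicates.
#' @export
flag_activity_outliers <- function(f_A, k = 5) {
  med <- median(f_A)
  dev <- mad(f_A)
  if (dev == 0) dev <- 1e-12
  f_A > med + k * dev
}

#' Detect kinetically trapped "pocket" domains
#'
#' Two detectors, both reported. Structural: a four-connected cluster of the
#' ordered phase (ordered lipids plus embedded order-preferring inclusions)
#' containing at least one active target and one activator but no
#' inactivator, persisting across at least `T_persist` consecutive snapshots
#' with at least `min_overlap` site overlap, is a pocket event.
#' Distributional: replicates whose activity exceeds the replicate median by
#' more than `k` MADs are flagged (see [flag_activity_outliers()]).
#' Activator/inactivator roles are read from the network: actors of
#' activating (+1) and deactivating (-1) rules respectively.
#'
#' @param x A `sim_result` with snapshots, a list of `lattice_state`
#'   snapshots, or `NULL` (distributional detector only).
#' @param activity Optional numeric vector of per-replicate activities for
#'   the distributional detector.
#' @param T_persist Minimum persistence in consecutive snapshots.
#' @param min_overlap Minimum fractional site overlap linking a cluster
#'   across consecutive snapshots.
#' @param k MAD multiplier for the outlier flag.
#' @return List with `events` (tibble: first_snapshot, last_snapshot,
#'   persistence, size), `n_events`, and `outliers` (logical vector or
#'   `NULL`). When no snapshots are supplied the structural detector is
#'   skipped with a warning.
#' @export
detect_pockets <- function(x, activity = NULL, T_persist = 3L,
                           min_overlap = 0.5, k = 5) {
  snaps <- if (inherits(x, "sim_result")) x$snapshots else x
  events <- tibble::tibble(first_snapshot = integer(),
                           last_snapshot = integer(),
                           persistence = integer(), size = integer())
  if (is.null(snaps) || length(snaps) == 0L) {
    warning("no snapshots: structural pocket detector unavailable")
  } else {
    network <- snaps[[1]]$network
    rule_sign <- vapply(network$rules, function(r) r$activity_sign, integer(1))
    rule_actor <- vapply(network$rules, function(r) r$actor, character(1))
    activators <- unique(rule_actor[rule_sign > 0L])
    inactivators <- unique(rule_actor[rule_sign < 0L])
    # qualifying clusters (site sets) per snapshot
    qual <- lapply(snaps, function(sn) {
      lab <- label_ordered_clusters(sn)
      inc <- sn$inclusions
      out <- list()
      for (cl in setdiff(unique(as.vector(lab)), 0L)) {
        sites <- which(lab == cl)
        ids <- setdiff(unique(sn$occupancy[sites]), 0L)
        memb <- inc[inc$id %in% ids, , drop = FALSE]
        n_act_tgt <- sum(memb$component == network$target &
                           memb$state == network$active_state)
        n_activ <- sum(memb$component %in% activators)
        n_inact <- sum(memb$component %in% inactivators)
        if (n_act_tgt >= 1L && n_activ >= 1L && n_inact == 0L) {
          out[[length(out) + 1L]] <- sites
        }
      }
      out
    })
    # chain qualifying clusters across consecutive snapshots by overlap
    open <- list()  # each: list(first, sites)
    for (t in seq_along(qual)) {
      matched <- rep(FALSE, length(qual[[t]]))
      nxt <- list()
      for (ch in open) {
        hit <- 0L
        for (q in seq_along(qual[[t]])) {
          if (matched[q]) next
          ov <- length(intersect(ch$sites, qual[[t]][[q]])) /
            length(ch$sites)
          if (ov >= min_overlap) {
            hit <- q
            break
          }
        }
        if (hit > 0L) {
          matched[hit] <- TRUE
          nxt[[length(nxt) + 1L]] <- list(first = ch$first,
                                          sites = qual[[t]][[hit]])
        } else if (t - ch$first >= T_persist) {
          events <- rbind(events, tibble::tibble(
            first_snapshot = ch$first, last_snapshot = t - 1L,
            persistence = t - ch$first, size = length(ch$sites)))
        }
      }
      for (q in which(!matched)) {
        nxt[[length(nxt) + 1L]] <- list(first = t, sites = qual[[t]][[q]])
      }
      open <- nxt
    }
    n_snap <- length(qual)
    for (ch in open) {
      if (n_snap - ch$first + 1L >= T_persist) {
        events <- rbind(events, tibble::tibble(
          first_snapshot = ch$first, last_snapshot = n_snap,
          persistence = n_snap - ch$first + 1L, size = length(ch$sites)))
      }
    }
  }
  outliers <- if (!is.null(activity)) flag_activity_outliers(activity, k)
  list(events = events, n_events = nrow(events), outliers = outliers)
}

#' Histogram of per-replicate activities
#'
#' Bins replicate activities with a Freedman-Diaconis default bin width,
#' useful for seeing the bimodality produced by pocketing runs.
#'
#' @param f_A Numeric vector of activities.
#' @param bin_width Bin width; `NULL` for Freedman-Diaconis.
#' @return Tibble with `mid` (bin centre) and `count`.
#' @export
bin_activity <- function(f_A, bin_width = NULL) {
  if (is.null(bin_width)) {
    iqr <- stats::IQR(f_A)
    bin_width <- if (iqr > 0) 2 * iqr / length(f_A)^(1 / 3) else 0.05
  }
  lo <- floor(min(f_A) / bin_width) * bin_width
  breaks <- seq(lo, max(f_A) + bin_width, by = bin_width)
  h <- graphics::hist(f_A, breaks = breaks, plot = FALSE)
  tibble::tibble(mid = h$mids, count = h$counts)
}
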