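#' Pair of spatial COP features used for gain identification
#'
#' @param lean_max maximal toward-target COP displacement after the reach,
#'   cm (>= 0).
#' @param apa_size peak-to-peak COP displacement within the APA phase, cm
#'   (>= 0).
#' @return A list of class `feature_pair`.
#' @export
feature_pair <- function(lean_max, apa_size) {
  check_number(lean_max, "lean_max", 0)
  check_number(apa_size, "apa_size", 0)
  structure(list(lean_max = lean_max, apa_size = apa_size),
            class = "feature_pair")
}

# Build a memoised evaluator mapping (K_P, K_FF) to simulated features for
# a fixed plan/plant/anthropometry. The trial timeline (analytic reference)
# is built once and reused across gain evaluations.
.make_feature_evaluator <- function(anthro, plant, params,
                                    config = sim_config(),
                                    seg_config = segment_config()) {
  timeline <- .build_timeline(params, config)
  keep <- seq(1L, timeline$n_steps + 1L, by = timeline$decim)
  time <- (keep - 1L) * config$dt
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  eval_fn <- function(K_P, K_FF) {
    counter$n <- counter$n + 1L
    gains <- control_gains(K_P = K_P, K_FF = K_FF)
    raw <- tryCatch(
      .run_closed_loop(timeline, anthro, plant, gains, params, config),
      leansim_error_unstable_gains = function(e) NULL,
      leansim_error_diverged = function(e) NULL)
    if (is.null(raw)) return(NULL)
    s <- raw$cop_m[keep] * 100
    seg <- tryCatch(
      .segment_signal(s, time, timeline$onset, seg_config),
      leansim_error_no_apa = function(e) NULL,
      leansim_error_segmentation = function(e) NULL)
    if (is.null(seg)) return(NULL)
    list(lean_max = seg$lean_max, apa_size = seg$apa_size, seg = seg)
  }
  list(eval = eval_fn, counter = counter)
}

#' Response surfaces of the two COP features over a gain grid
#'
#' Simulates and segments a noiseless trial at every (K_P, K_FF) grid point
#' and returns the Lean_max and APA-size response surfaces. Grid points
#' whose closed loop is statically unstable (or whose simulation diverges)
#' are recorded as `NA`.
#'
#' @param anthro,plant,params model set-up as in [simulate_trial()].
#' @param K_P_grid,K_FF_grid numeric grids of gains (N m/deg and
#'   dimensionless).
#' @param config,seg_config simulation and segmentation configuration.
#' @return A list of class `feature_surface` with matrices `lean_max` and
#'   `apa_size` (rows = `K_P_grid`, columns = `K_FF_grid`) and the grids.
#' @export
feature_surface <- function(anthro, plant, params, K_P_grid, K_FF_grid,
                            config = sim_config(),
                            seg_config = segment_config()) {
  ev <- .make_feature_evaluator(anthro, plant, params, config, seg_config)
  lean <- matrix(NA_real_, length(K_P_grid), length(K_FF_grid),
                 dimnames = list(K_P_grid, K_FF_grid))
  apa <- lean
  for (i in seq_along(K_P_grid)) {
    for (j in seq_along(K_FF_grid)) {
      f <- ev$eval(K_P_grid[i], K_FF_grid[j])
      if (!is.null(f)) {
        lean[i, j] <- f$lean_max
        apa[i, j] <- f$apa_size
      }
    }
  }
  if (all(is.na(lean))) {
    ls_abort("empty surface: every grid point was closed-loop unstable",
             "leansim_error_empty_surface")
  }
  structure(list(lean_max = lean, apa_size = apa,
                 K_P_grid = K_P_grid, K_FF_grid = K_FF_grid),
            class = "feature_surface")
}

#' Options for gain identification
#'
#' @param bounds_K_P,bounds_K_FF search bounds; the defaults enclose the
#'   physiologic range of both groups with margin.
#' @param grid_n number of multi-start grid points per gain (default 5).
#' @param n_local number of best grid starts refined by bounded local
#'   optimization.
#' @param tol convergence tolerance on the combined normalized residual.
#' @param scales normalization scales `c(lean, apa)` for the objective;
#'   `NULL` uses the target feature values (falling back to 1 where a
#'   target is zero).
#' @param method `"ls"` (bounded least squares, default) or `"root"`
#'   (damped Newton root finding on the two residuals, falling back to
#'   `"ls"` when it does not converge).
#' @param sim_config,seg_config simulation / segmentation configuration.
#' @return A list of class `identify_options`.
#' @export
identify_options <- function(bounds_K_P = c(5, 300), bounds_K_FF = c(0, 30),
                             grid_n = 5, n_local = 3, tol = 1e-2,
                             scales = NULL, method = c("ls", "root"),
                             sim_config = leansim::sim_config(),
                             seg_config = leansim::segment_config()) {
  method <- match.arg(method)
  structure(list(bounds_K_P = bounds_K_P, bounds_K_FF = bounds_K_FF,
                 grid_n = grid_n, n_local = n_local, tol = tol,
                 scales = scales, method = method,
                 sim_config = sim_config, seg_config = seg_config),
            class = "identify_options")
}

#' Identify subject-specific control gains from the two COP features
#'
#' Finds the gains (K_P, K_FF) whose simulated trial reproduces the
#' measured Lean_max and APA size. The temporal plan (`params`) is fixed
#' from the segmentation of the subject's own data; the two gains are the
#' only free variables. The normalized residuals
#' `|Lean_max(model) - Lean_max(target)| / s_lean` and
#' `|APA(model) - APA(target)| / s_apa` are minimized simultaneously:
#' by default their sum of squares, via bounded local optimization
#' (`nlminb`) multi-started from a deterministic coarse grid; optionally by
#' exact two-equation root finding when the target is interior to the
#' feature surface. Ties between equally good optima are broken toward the
#' smallest K_P, then K_FF.
#'
#' @param target a [feature_pair] (or list with `lean_max` and `apa_size`
#'   in cm).
#' @param anthro,plant,params model set-up; `params` holds the measured
#'   temporal parameters.
#' @param options an [identify_options] list.
#' @return An object of class `identification_result` with fields `K_P`,
#'   `K_FF`, `residual_lean`, `residual_apa` (cm, model minus target),
#'   `objective` (combined normalized L1 residual), `n_evals`, `converged`,
#'   `bounds_hit` and the multi-start bookkeeping (`starts`).
#' @export
identify_gains <- function(target, anthro, plant, params,
                           options = identify_options()) {
  if (!all(is.finite(c(target$lean_max, target$apa_size)))) {
    ls_abort("target features must be finite", "leansim_error_validation")
  }
  scales <- options$scales
  if (is.null(scales)) {
    scales <- c(lean = if (target$lean_max > 0) target$lean_max else 1,
                apa = if (target$apa_size > 0) target$apa_size else 1)
  }
  ev <- .make_feature_evaluator(anthro, plant, params,
                                options$sim_config, options$seg_config)
  resid <- function(k) {
    f <- ev$eval(k[1], k[2])
    if (is.null(f)) return(NULL)
    c((f$lean_max - target$lean_max) / scales[["lean"]],
      (f$apa_size - target$apa_size) / scales[["apa"]])
  }
  obj2 <- function(k) {
    r <- resid(k)
    if (is.null(r)) return(1e6)
    sum(r^2)
  }

  lo <- c(options$bounds_K_P[1], options$bounds_K_FF[1])
  hi <- c(options$bounds_K_P[2], options$bounds_K_FF[2])
  kp_pts <- seq(lo[1], hi[1], length.out = options$grid_n)
  kff_pts <- seq(lo[2], hi[2], length.out = options$grid_n)
  starts <- expand.grid(K_P = kp_pts, K_FF = kff_pts,
                        KEEP.OUT.ATTRS = FALSE)
  starts$objective <- apply(starts, 1, function(k) obj2(as.numeric(k)))
  feasible <- starts$objective < 1e6
  if (!any(feasible)) {
    ls_abort("identification infeasible: no stable multi-start point",
             "leansim_error_infeasible")
  }
  # seed additional starts by exploiting the monotone growth of APA size
  # with K_FF: along each stable K_P row, bisect K_FF to match the target
  # APA size, which places a start inside the narrow valley the coarse
  # grid straddles
  apa_of <- function(kp, kff) {
    f <- ev$eval(kp, kff)
    if (is.null(f)) NA_real_ else f$apa_size
  }
  seeded <- list()
  for (kp in kp_pts) {
    a_lo <- apa_of(kp, lo[2]); a_hi <- apa_of(kp, hi[2])
    if (!is.finite(a_lo) || !is.finite(a_hi)) next
    if (target$apa_size <= a_lo) {
      kff_star <- lo[2]
    } else if (target$apa_size >= a_hi) {
      kff_star <- hi[2]
    } else {
      l <- lo[2]; u <- hi[2]
      for (it in 1:20) {
        mid <- (l + u) / 2
        a_mid <- apa_of(kp, mid)
        if (!is.finite(a_mid)) break
        if (a_mid < target$apa_size) l <- mid else u <- mid
      }
      kff_star <- (l + u) / 2
    }
    seeded[[length(seeded) + 1L]] <- data.frame(
      K_P = kp, K_FF = kff_star, objective = obj2(c(kp, kff_star)))
  }
  if (length(seeded) > 0) starts <- rbind(starts, do.call(rbind, seeded))
  feasible <- starts$objective < 1e6
  ord <- order(starts$objective, starts$K_P, starts$K_FF)
  best_starts <- ord[feasible[ord]][seq_len(min(options$n_local,
                                                sum(feasible)))]

  # bounded quasi-Newton with finite-difference steps large enough to see
  # past the sample-quantization kinks of the features, then a derivative-
  # free Nelder-Mead polish (bounds enforced by clamping)
  local_fit <- function(start) {
    fit <- optim(start, obj2, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(parscale = c(50, 5), ndeps = c(1e-3, 1e-3),
                                factr = 1e4, maxit = 200))
    par <- fit$par
    if (fit$value > 1e-10) {
      obj_clamped <- function(k) obj2(pmin(pmax(k, lo), hi))
      pol <- optim(par, obj_clamped, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 300))
      par <- pmin(pmax(pol$par, lo), hi)
    }
    list(par = par, objective = obj2(par))
  }
  candidates <- lapply(best_starts, function(i) {
    local_fit(as.numeric(starts[i, c("K_P", "K_FF")]))
  })

  if (options$method == "root") {
    rt <- .newton_root(resid, candidates[[1]]$par, lo, hi)
    if (!is.null(rt)) {
      candidates <- c(candidates, list(list(par = rt, objective = obj2(rt))))
    }
  }

  objs <- vapply(candidates, `[[`, numeric(1), "objective")
  kps <- vapply(candidates, function(c) c$par[1], numeric(1))
  kffs <- vapply(candidates, function(c) c$par[2], numeric(1))
  # tie-break equally good optima toward smallest K_P, then K_FF; optima
  # matching the features to well below the identification tolerance are
  # treated as ties (the feature map can be non-injective at high K_P,
  # where Lean_max saturates)
  pick <- order(round(objs, 6), kps, kffs)[1]
  par <- candidates[[pick]]$par

  f <- ev$eval(par[1], par[2])
  if (is.null(f)) {
    ls_abort("identification infeasible: returned point not simulable",
             "leansim_error_infeasible")
  }
  r_lean <- f$lean_max - target$lean_max
  r_apa <- f$apa_size - target$apa_size
  obj_l1 <- abs(r_lean) / scales[["lean"]] + abs(r_apa) / scales[["apa"]]
  eps <- 1e-6 * (hi - lo)
  bounds_hit <- c(K_P_lower = par[1] <= lo[1] + eps[1],
                  K_P_upper = par[1] >= hi[1] - eps[1],
                  K_FF_lower = par[2] <= lo[2] + eps[2],
                  K_FF_upper = par[2] >= hi[2] - eps[2])

  structure(list(
    K_P = par[1], K_FF = par[2],
    residual_lean = r_lean, residual_apa = r_apa,
    objective = obj_l1, n_evals = ev$counter$n,
    converged = obj_l1 < options$tol,
    bounds_hit = bounds_hit,
    starts = starts, scales = scales,
    features = list(lean_max = f$lean_max, apa_size = f$apa_size)
  ), class = "identification_result")
}

# damped Newton iteration on the two normalized residuals; returns NULL
# when it leaves the bounds or fails to contract
.newton_root <- function(resid, start, lo, hi, max_iter = 30,
                         tol = 1e-10) {
  k <- start
  r <- resid(k)
  if (is.null(r)) return(NULL)
  for (it in seq_len(max_iter)) {
    if (sum(r^2) < tol^2) return(k)
    h <- pmax(1e-4 * abs(k), 1e-4)
    jac <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      kp <- k; kp[j] <- min(kp[j] + h[j], hi[j])
      km <- k; km[j] <- max(km[j] - h[j], lo[j])
      rp <- resid(kp); rm <- resid(km)
      if (is.null(rp) || is.null(rm)) return(NULL)
      jac[, j] <- (rp - rm) / (kp[j] - km[j])
    }
    step <- tryCatch(solve(jac, -r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      k_new <- pmin(pmax(k + lambda * step, lo), hi)
      r_new <- resid(k_new)
      if (!is.null(r_new) && sum(r_new^2) < sum(r^2)) break
      lambda <- lambda / 2
      if (lambda < 1e-4) return(NULL)
    }
    k <- k_new
    r <- r_new
  }
  if (sum(r^2) < tol^2) k else NULL
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "<identification> K_P = %.3f N m/deg, K_FF = %.3f (objective %.2e, %d evals, %s)\n",
    x$K_P, x$K_FF, x$objective, x$n_evals,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}
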