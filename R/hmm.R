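#' Two-behaviour movement model
#'
#' Diffusivities (km^2/day) for the resident and migratory behaviour
#' states and the row-stochastic 2x2 behaviour switch matrix. The
#' per-axis variance of the daily displacement kernel is `2 * D * dt`.
#'
#' @param D_res,D_mig diffusivities, `0 <= D_res <= D_mig`.
#' @param switch_matrix 2x2 row-stochastic matrix, rows/cols ordered
#'   (resident, migratory).
#' @return a `behaviour_model` list.
#' @export
behaviour_model <- function(D_res = 5, D_mig = 120,
                            switch_matrix = matrix(c(0.95, 0.05, 0.10, 0.90),
                                                   2, 2, byrow = TRUE)) {
  if (D_res < 0 || D_mig < 0) stop("diffusivities must be nonnegative")
  if (D_res > D_mig) stop("D_res must not exceed D_mig")
  if (any(switch_matrix < 0) || any(abs(rowSums(switch_matrix) - 1) > 1e-8))
    stop("switch_matrix must be row-stochastic")
  structure(list(D_res = D_res, D_mig = D_mig,
                 switch_matrix = switch_matrix),
            class = "behaviour_model")
}

# banded 1-D Gaussian weight matrix; truncation at ceil(4 sd) cells
gauss_band <- function(n, sd_cells) {
  if (sd_cells <= 0) return(diag(n))
  k <- ceiling(4 * sd_cells)
  i <- matrix(seq_len(n), n, n)
  d <- i - t(i)
  w <- exp(-d^2 / (2 * sd_cells^2))
  w[abs(d) > k] <- 0
  w
}

#' Daily diffusion transition operator
#'
#' Gaussian spatial diffusion on the grid with per-axis variance
#' `2 D dt` km^2, truncated per axis at 4 sd, with land cells excluded
#' and probability renormalised (mass that would diffuse onto land or
#' off the grid is redistributed by column normalisation). `D = 0`
#' yields the identity.
#'
#' @param env an `env_grid`.
#' @param D diffusivity (km^2/day), nonnegative.
#' @param dt time step in days.
#' @return a `diffusion_kernel` list with the banded row/column factor
#'   matrices, the normaliser `Z`, and the truncation radius in cells.
#' @export
diffusion_kernel <- function(env, D, dt = 1) {
  if (D < 0) stop("diffusivity must be nonnegative")
  sd_cells <- sqrt(2 * D * dt) / env$cell_km
  Grow <- gauss_band(env$ny, sd_cells)
  Gcol <- gauss_band(env$nx, sd_cells)
  sea <- matrix(as.numeric(env$sea), env$ny, env$nx)
  Z <- Grow %*% sea %*% Gcol
  structure(list(Grow = Grow, Gcol = Gcol, Z = Z, sea = sea,
                 D = D, dt = dt, sd_cells = sd_cells,
                 k = if (sd_cells > 0) ceiling(4 * sd_cells) else 0L),
            class = "diffusion_kernel")
}

#' Apply a diffusion kernel to a probability surface
#'
#' @param kern a `diffusion_kernel`.
#' @param M surface (ny x nx matrix).
#' @param transpose apply the transpose operator (used by the backward
#'   recursion) instead.
#' @return the diffused surface.
#' @export
apply_kernel <- function(kern, M, transpose = FALSE) {
  if (!transpose) {
    u <- M / kern$Z
    u[kern$sea == 0 | !is.finite(u)] <- 0
    (kern$Grow %*% u %*% kern$Gcol) * kern$sea
  } else {
    v <- (kern$Grow %*% (M * kern$sea) %*% kern$Gcol) / kern$Z
    v[kern$sea == 0 | !is.finite(v)] <- 0
    v
  }
}

# shared setup for the C++ filters
hmm_inputs <- function(lik_stack, env, model, init = NULL,
                       binit = c(0.5, 0.5)) {
  arr <- if (inherits(lik_stack, "lik_stack")) lik_stack$arr else lik_stack
  Ds <- c(model$D_res, model$D_mig)
  sdc <- sqrt(2 * Ds) / env$cell_km
  Grow <- lapply(sdc, function(s) gauss_band(env$ny, s))
  Gcol <- lapply(sdc, function(s) gauss_band(env$nx, s))
  if (is.null(init)) {
    init <- arr[, , 1] * 0 + as.numeric(env$sea)
    init <- init / sum(init)
  }
  list(arr = arr, Grow = Grow, Gcol = Gcol,
       sea = matrix(as.numeric(env$sea), env$ny, env$nx),
       init = init, binit = binit, sdc = sdc,
       k = as.integer(ifelse(sdc > 0, ceiling(4 * sdc), 0)))
}

#' Forward-backward smoothing over the joint (cell, behaviour) state
#'
#' Standard scaled HMM filter/smoother. The initial spatial
#' distribution defaults to uniform over sea; in practice the day-1
#' likelihood carries the release anchor. Daily scaling constants are
#' retained and their logs sum to the data log-likelihood.
#'
#' @param lik_stack a `lik_stack` (or a ny x nx x n_days array).
#' @param env an `env_grid`.
#' @param model a `behaviour_model`.
#' @param init optional initial spatial surface.
#' @param binit initial behaviour distribution.
#' @return a `posterior_track`: `smoothed` (ny x nx x nd, cell
#'   marginals), `behaviour_prob` (nd x 2), `smoothed_res` (joint
#'   marginal of the resident state), `loglik`, `log_c`.
#' @export
forward_backward <- function(lik_stack, env, model, init = NULL,
                             binit = c(0.5, 0.5)) {
  inp <- hmm_inputs(lik_stack, env, model, init, binit)
  res <- bg_forward(inp$arr, inp$init, inp$binit, model$switch_matrix,
                    inp$Grow, inp$Gcol, inp$sea, TRUE)
  if (!isTRUE(res$ok))
    stop("likelihood vanished on day ", res$bad_day,
         ": no admissible state survives")
  structure(list(smoothed = res$smoothed,
                 smoothed_res = res$smoothed_res,
                 behaviour_prob = res$behaviour,
                 loglik = res$loglik, log_c = res$logc,
                 days = if (inherits(lik_stack, "lik_stack"))
                   lik_stack$days else seq_len(dim(inp$arr)[3]),
                 model = model),
            class = "posterior_track")
}

#' Forward log-likelihood only (no smoothing)
#' @inheritParams forward_backward
#' @return the data log-likelihood (scalar; `-Inf` if some day's
#'   likelihood vanishes).
#' @export
forward_loglik <- function(lik_stack, env, model, init = NULL,
                           binit = c(0.5, 0.5)) {
  inp <- hmm_inputs(lik_stack, env, model, init, binit)
  res <- bg_forward(inp$arr, inp$init, inp$binit, model$switch_matrix,
                    inp$Grow, inp$Gcol, inp$sea, FALSE)
  if (!isTRUE(res$ok)) return(-Inf)
  res$loglik
}

#' Estimate diffusivities and switching by maximum likelihood
#'
#' Bounded derivative-free search (Nelder-Mead on log-diffusivities and
#' logit switch probabilities) of the forward log-likelihood, with
#' multiple starts. The two diffusivities are label-ordered so
#' `D_res <= D_mig` on return. When the two estimates collapse
#' (ratio < 1.5) the switch parameters are flagged unidentifiable.
#'
#' @param lik_stack a `lik_stack`.
#' @param env an `env_grid`.
#' @param init a `behaviour_model` used as the search start.
#' @param bounds diffusivity bounds (km^2/day).
#' @param nstart number of Nelder-Mead starts (the first from `init`,
#'   the rest from seeded perturbations).
#' @param maxit,reltol passed to [stats::optim()].
#' @param seed seed for the start perturbations.
#' @return a `behaviour_model` with attributes `loglik`, `convergence`,
#'   `unidentifiable_switch`, `n_eval`.
#' @export
estimate_parameters <- function(lik_stack, env,
                                init = behaviour_model(10, 50),
                                bounds = c(0.5, 500), nstart = 3,
                                maxit = 300, reltol = 1e-5, seed = 1) {
  lb <- log(bounds[1]); ub <- log(bounds[2])
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  unpack <- function(th) {
    D <- sort(exp(clamp(th[1:2], lb, ub)))
    p11 <- 1 / (1 + exp(-clamp(th[3], -8, 8)))
    p22 <- 1 / (1 + exp(-clamp(th[4], -8, 8)))
    behaviour_model(D[1], D[2],
                    matrix(c(p11, 1 - p11, 1 - p22, p22), 2, 2,
                           byrow = TRUE))
  }
  nege <- 0L
  obj <- function(th) {
    nege <<- nege + 1L
    -forward_loglik(lik_stack, env, unpack(th))
  }
  sw <- init$switch_matrix
  th0 <- c(log(clamp(init$D_res, bounds[1], bounds[2])),
           log(clamp(init$D_mig, bounds[1], bounds[2])),
           log(sw[1, 1] / (1 - sw[1, 1])), log(sw[2, 2] / (1 - sw[2, 2])))
  if (!is.finite(obj(th0)))
    stop("log-likelihood not finite at the initial model")
  set.seed(as.integer(seed))
  starts <- list(th0)
  if (nstart > 1)
    for (i in 2:nstart)
      starts[[i]] <- th0 + rnorm(4, 0, c(1, 1, 0.75, 0.75))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out <- unpack(best$par)
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  attr(out, "unidentifiable_switch") <- out$D_mig < 1.5 * out$D_res
  attr(out, "n_eval") <- nege
  out
}

#' Most probable track (Viterbi decoding)
#'
#' Joint maximum a posteriori sequence over the (cell, behaviour)
#' state; this is the "most probable track" and need not coincide with
#' the sequence of daily marginal modes. Ties are broken toward the
#' lower cell index.
#'
#' @inheritParams forward_backward
#' @return data.frame (day, cell, row, col, lon, lat, behaviour) with
#'   attribute `logprob`, the joint log-probability of the path.
#' @export
viterbi <- function(lik_stack, env, model, init = NULL,
                    binit = c(0.5, 0.5)) {
  inp <- hmm_inputs(lik_stack, env, model, init, binit)
  res <- bg_viterbi(inp$arr, inp$init, inp$binit, model$switch_matrix,
                    inp$sdc, inp$k, inp$Grow, inp$Gcol, inp$sea)
  cells <- as.integer(res$cells)
  rc <- cell_rc(env, cells)
  ll <- cell_lonlat(env, cells)
  days <- if (inherits(lik_stack, "lik_stack")) lik_stack$days
  else seq_along(cells)
  out <- data.frame(day = days, cell = cells,
                    row = rc[, "row"], col = rc[, "col"],
                    lon = ll[, "lon"], lat = ll[, "lat"],
                    behaviour = c("resident", "migratory")[res$behaviours])
  attr(out, "logprob") <- res$logprob
  out
}

#' Daily most-probable positions with uncertainty
#'
#' Per-day argmax of the smoothed cell marginal plus the area (km^2) of
#' the 95% highest-posterior-density cell set as the uncertainty
#' summary. Ties are resolved to the northernmost, then westernmost,
#' cell and flagged.
#'
#' @param post a `posterior_track`.
#' @param env an `env_grid`.
#' @param hpd HPD mass (default 0.95).
#' @return data.frame: day, cell, row, col, lon, lat, p_mode,
#'   hpd_area_km2, tie.
#' @export
mode_positions <- function(post, env, hpd = 0.95) {
  nd <- dim(post$smoothed)[3]
  cell_area <- env$cell_km^2
  out <- vector("list", nd)
  for (t in seq_len(nd)) {
    w <- post$smoothed[, , t]
    mx <- max(w)
    cand <- which(w == mx)
    tie <- length(cand) > 1
    if (tie) {
      rc <- cell_rc(env, cand)
      o <- order(-rc[, "row"], rc[, "col"])
      cand <- cand[o]
    }
    cell <- cand[1]
    sw <- sort(as.numeric(w), decreasing = TRUE)
    n_hpd <- which(cumsum(sw) >= hpd * sum(sw))[1]
    rc1 <- cell_rc(env, cell)
    out[[t]] <- data.frame(day = post$days[t], cell = cell,
                           row = rc1[, "row"], col = rc1[, "col"],
                           lon = env$lon[rc1[, "col"]],
                           lat = env$lat[rc1[, "row"]],
                           p_mode = mx,
                           hpd_area_km2 = n_hpd * cell_area,
                           tie = tie)
  }
  do.call(rbind, out)
}

#' Joint log-probability of an explicit path under the model
#'
#' Used to verify Viterbi dominance over the sequence of daily modes.
#'
#' @param lik_stack a `lik_stack` or array.
#' @param env an `env_grid`.
#' @param model a `behaviour_model`.
#' @param cells integer cell sequence (one per day).
#' @param behaviours behaviour sequence (`"resident"`/`"migratory"` or
#'   1/2).
#' @inheritParams forward_backward
#' @return joint log-probability (can be `-Inf`).
#' @export
path_logprob <- function(lik_stack, env, model, cells, behaviours,
                         init = NULL, binit = c(0.5, 0.5)) {
  inp <- hmm_inputs(lik_stack, env, model, init, binit)
  if (is.character(behaviours))
    behaviours <- match(behaviours, c("resident", "migratory"))
  nd <- dim(inp$arr)[3]
  kerns <- list(diffusion_kernel(env, model$D_res),
                diffusion_kernel(env, model$D_mig))
  lp <- log(inp$binit[behaviours[1]]) + log(inp$init[cells[1]]) +
    log(inp$arr[, , 1][cells[1]])
  for (t in 2:nd) {
    b2 <- behaviours[t]
    kern <- kerns[[b2]]
    rc1 <- cell_rc(env, cells[t - 1]); rc2 <- cell_rc(env, cells[t])
    dr <- abs(rc2[, "row"] - rc1[, "row"])
    dc <- abs(rc2[, "col"] - rc1[, "col"])
    if (kern$sd_cells == 0) {
      g <- if (dr == 0 && dc == 0) 1 else 0
    } else if (dr > kern$k || dc > kern$k) {
      g <- 0
    } else {
      g <- exp(-(dr^2 + dc^2) / (2 * kern$sd_cells^2))
    }
    ktrans <- g * inp$sea[cells[t]] / kern$Z[cells[t - 1]]
    lp <- lp + log(model$switch_matrix[behaviours[t - 1], b2]) +
      log(ktrans) + log(inp$arr[, , t][cells[t]])
  }
  unname(lp)
}
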