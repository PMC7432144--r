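#' Design of a synthetic elicitation experiment
#'
#' Describes the factorial layout of an elicitation experiment on a plant cell
#' suspension culture: elicitor blends (cell extract CE : culture filtrate CF
#' volume ratios, plus water:PDB control blends that carry no elicitor), total
#' elicitor concentrations (% v/v), elicitor adding days, and harvests at a
#' fixed interval after elicitation up to a final culture day, replicated in
#' blocks. The default reproduces a randomized complete block factorial with
#' 10 blend levels (5 elicitor ratios and 5 matching controls), concentrations
#' 2.5/5/10 % v/v, adding days 13 and 17, harvests every 2 days until day 23,
#' and 3 replicates: 720 flask observations.
#'
#' @param blend_levels data frame with columns `ce_frac`, `cf_frac`
#'   (non-negative fractions summing to 1 per row) and logical `control`.
#'   Control blends are inert: their CE and CF doses are coded 0 whatever the
#'   nominal volume added.
#' @param conc_levels total blend concentrations, % v/v.
#' @param adding_days culture days on which the elicitor is added.
#' @param harvest_interval_days days between successive harvests.
#' @param final_day last culture day harvested (inclusive).
#' @param n_replicates number of blocks (replicate flask series).
#' @return an object of class `design_config`.
#' @seealso [generate_design()], [surface_params()]
#' @export
design_config <- function(blend_levels = default_blend_levels(),
                          conc_levels = c(2.5, 5, 10),
                          adding_days = c(13, 17),
                          harvest_interval_days = 2,
                          final_day = 23,
                          n_replicates = 3) {
  if (!is.data.frame(blend_levels) ||
      !all(c("ce_frac", "cf_frac", "control") %in% names(blend_levels)))
    stopf("'blend_levels' must be a data frame with ce_frac, cf_frac, control")
  if (nrow(blend_levels) == 0L || length(conc_levels) == 0L ||
      length(adding_days) == 0L)
    stopf("configuration error: empty factor level list")
  fr <- blend_levels$ce_frac + blend_levels$cf_frac
  if (any(blend_levels$ce_frac < 0) || any(blend_levels$cf_frac < 0) ||
      any(abs(fr - 1) > 1e-8))
    stopf("each blend ratio pair must be non-negative and sum to 1")
  if (any(conc_levels <= 0)) stopf("'conc_levels' must be positive")
  check_number(harvest_interval_days, "harvest_interval_days", lower = 1)
  check_number(final_day, "final_day")
  check_number(n_replicates, "n_replicates", lower = 1)
  if (final_day <= max(adding_days))
    stopf("configuration error: final_day (%s) must exceed every adding day",
          final_day)
  structure(
    list(blend_levels = blend_levels, conc_levels = as.numeric(conc_levels),
         adding_days = as.numeric(adding_days),
         harvest_interval_days = as.numeric(harvest_interval_days),
         final_day = as.numeric(final_day),
         n_replicates = as.integer(n_replicates)),
    class = "design_config")
}

#' @rdname design_config
#' @export
default_blend_levels <- function() {
  ratios <- rbind(c(1, 0), c(0.75, 0.25), c(0.5, 0.5), c(0.25, 0.75), c(0, 1))
  data.frame(
    ce_frac = rep(ratios[, 1], 2),
    cf_frac = rep(ratios[, 2], 2),
    control = rep(c(FALSE, TRUE), each = 5)
  )
}

#' Enumerate the flask observations of a factorial elicitation design
#'
#' Expands a [design_config()] into one row per (blend, concentration, adding
#' day, harvest day, replicate) combination with empty response columns.
#' Harvest days are `adding_day + k * harvest_interval_days` up to
#' `final_day`; doses are `ce_conc = ce_frac * concentration` (0 for control
#' blends), likewise `cf_conc`.
#'
#' @param config a [design_config()].
#' @return a data frame with columns `ce_conc`, `cf_conc`, `adding_day`,
#'   `harvest_day`, `replicate` and `NA` response columns `dw`, `intra`,
#'   `extra`, `total`, `portion`.
#' @examples
#' nrow(generate_design(design_config()))  # 720
#' @export
generate_design <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  rows <- list()
  bl <- config$blend_levels
  for (b in seq_len(nrow(bl))) {
    for (conc in config$conc_levels) {
      for (a in config$adding_days) {
        harvests <- seq(a + config$harvest_interval_days, config$final_day,
                        by = config$harvest_interval_days)
        for (r in seq_len(config$n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            ce_conc = if (bl$control[b]) 0 else bl$ce_frac[b] * conc,
            cf_conc = if (bl$control[b]) 0 else bl$cf_frac[b] * conc,
            adding_day = a,
            harvest_day = harvests,
            replicate = r
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (resp in TABLE_RESPONSES) out[[resp]] <- NA_real_
  out
}

#' Ground-truth response surfaces for the synthetic experiment
#'
#' Parameterizes smooth noiseless response surfaces over (CE dose, CF dose,
#' adding day, harvest day) from which synthetic measurements are simulated:
#' logistic growth kinetics for dry weight with mild dose-proportional growth
#' inhibition; hump-shaped (bivariate Gaussian) CE/CF dose responses for
#' intracellular and extracellular paclitaxel, amplified by later elicitation
#' and modulated by harvest-day kinetics (transient peak for the intracellular
#' pool, saturating rise for secretion); total yield and extracellular portion
#' derived by the mass-balance identities `total = intra * dw + extra` and
#' `portion = 100 * extra / total`.
#'
#' Measurement noise is additive Gaussian, independent per response and row,
#' with standard deviation `noise_frac` times the standard deviation of the
#' noiseless response over the simulated design (overridable per response via
#' `noise_sd`); noisy responses are clipped at 0. `block_sd` adds an optional
#' per-replicate offset (same units as `noise_frac`) emulating block effects.
#'
#' @param dw,intra,extra named numeric vectors overriding individual surface
#'   parameters (see Details in the package vignette).
#' @param noise_frac noise sd as a fraction of each response's noiseless sd.
#' @param noise_sd optional named vector of absolute noise sds (response
#'   units) taking precedence over `noise_frac` for the named responses.
#' @param block_sd per-replicate random offset scale, as a fraction of each
#'   response's noiseless sd; 0 disables block effects.
#' @param seed default RNG seed used by [simulate_responses()].
#' @return an object of class `surface_params`.
#' @export
surface_params <- function(dw = NULL, intra = NULL, extra = NULL,
                           noise_frac = 0.1, noise_sd = NULL,
                           block_sd = 0, seed = NULL) {
  p <- list(
    dw = c(base = 2, max = 12.5, t_mid = 14, t_scale = 2.2,
           inhibition = 0.08, add_slope = 0.05),
    intra = c(base = 0.8, amplitude = 14, ce_opt = 3.4, cf_opt = 5.3,
              ce_width = 3.2, cf_width = 3.2, rho = -0.25,
              add_slope = 0.12, t_peak = 20, t_width = 3.2),
    extra = c(base = 1.5, amplitude = 80, ce_opt = 5.2, cf_opt = 5.7,
              ce_width = 3.5, cf_width = 3.5, rho = -0.2,
              add_slope = 0.10, t_mid = 19, t_scale = 1.8)
  )
  for (nm in names(dw)) p$dw[[nm]] <- dw[[nm]]
  for (nm in names(intra)) p$intra[[nm]] <- intra[[nm]]
  for (nm in names(extra)) p$extra[[nm]] <- extra[[nm]]
  check_number(noise_frac, "noise_frac", lower = 0)
  check_number(block_sd, "block_sd", lower = 0)
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd)) || !all(names(noise_sd) %in% TABLE_RESPONSES))
      stopf("'noise_sd' must be named after responses (%s)",
            paste(TABLE_RESPONSES, collapse = ", "))
    if (any(noise_sd < 0)) stopf("'noise_sd' must be non-negative")
  }
  for (surf in p)
    if (any(surf[grep("width|scale", names(surf))] <= 0))
      stopf("all width/scale parameters must be positive")
  structure(list(surfaces = p, noise_frac = noise_frac, noise_sd = noise_sd,
                 block_sd = block_sd, seed = seed),
            class = "surface_params")
}

# Correlated bivariate Gaussian dose-response hump, 1 at the optimum.
dose_bump <- function(ce, cf, p) {
  u <- (ce - p[["ce_opt"]]) / p[["ce_width"]]
  v <- (cf - p[["cf_opt"]]) / p[["cf_width"]]
  rho <- p[["rho"]]
  exp(-(u^2 - 2 * rho * u * v + v^2) / (2 * (1 - rho^2)))
}

#' Evaluate a noiseless ground-truth response surface
#'
#' @param params a [surface_params()].
#' @param ce,cf,adding_day,harvest_day numeric vectors (recycled to a common
#'   length) of input settings.
#' @param response one of `"dw"`, `"intra"`, `"extra"`, `"total"`, `"portion"`.
#' @return numeric vector of noiseless response values.
#' @export
true_response <- function(params, ce, cf, adding_day, harvest_day,
                          response = "total") {
  stopifnot(inherits(params, "surface_params"))
  response <- match.arg(response, TABLE_RESPONSES)
  n <- max(length(ce), length(cf), length(adding_day), length(harvest_day))
  ce <- rep_len(ce, n); cf <- rep_len(cf, n)
  a <- rep_len(adding_day, n); t <- rep_len(harvest_day, n)

  pd <- params$surfaces$dw
  dw <- (pd[["base"]] + (pd[["max"]] - pd[["base"]]) /
           (1 + exp(-(t - pd[["t_mid"]]) / pd[["t_scale"]]))) *
    (1 - pd[["inhibition"]] * (ce + cf) / 20) + pd[["add_slope"]] * (a - 15)
  if (response == "dw") return(dw)

  pi_ <- params$surfaces$intra
  intra <- pi_[["base"]] + pi_[["amplitude"]] * dose_bump(ce, cf, pi_) *
    (1 + pi_[["add_slope"]] * (a - 13)) *
    exp(-0.5 * ((t - pi_[["t_peak"]]) / pi_[["t_width"]])^2)
  if (response == "intra") return(intra)

  px <- params$surfaces$extra
  extra <- px[["base"]] + px[["amplitude"]] * dose_bump(ce, cf, px) *
    (1 + px[["add_slope"]] * (a - 13)) /
    (1 + exp(-(t - px[["t_mid"]]) / px[["t_scale"]]))
  if (response == "extra") return(extra)

  total <- intra * dw + extra
  if (response == "total") return(total)
  100 * extra / total
}

#' Simulate measured responses for a designed experiment
#'
#' Fills the five response columns of a design generated by
#' [generate_design()]: noiseless surfaces are evaluated via
#' [true_response()] (so `total` and `portion` satisfy their mass-balance
#' identities exactly before noise), then independent Gaussian measurement
#' noise is added to each reported response and values are clipped at 0.
#' Deterministic given `seed`.
#'
#' @param design data frame with the design input columns.
#' @param params a [surface_params()].
#' @param seed RNG seed; defaults to `params$seed`.
#' @return the design with response columns filled.
#' @export
simulate_responses <- function(design, params = surface_params(),
                               seed = params$seed) {
  stopifnot(inherits(params, "surface_params"))
  if (!all(TABLE_INPUTS %in% names(design)))
    stopf("design is missing input columns: %s",
          paste(setdiff(TABLE_INPUTS, names(design)), collapse = ", "))
  truth <- vapply(TABLE_RESPONSES, function(r)
    true_response(params, design$ce_conc, design$cf_conc,
                  design$adding_day, design$harvest_day, r),
    numeric(nrow(design)))
  sds <- apply(truth, 2, stats::sd)
  noise_sd <- params$noise_frac * sds
  if (!is.null(params$noise_sd))
    noise_sd[names(params$noise_sd)] <- params$noise_sd
  with_seed(seed, {
    for (j in seq_along(TABLE_RESPONSES)) {
      resp <- TABLE_RESPONSES[j]
      y <- truth[, j]
      if (params$block_sd > 0 && "replicate" %in% names(design)) {
        reps <- sort(unique(design$replicate))
        off <- stats::rnorm(length(reps), 0, params$block_sd * sds[j])
        y <- y + off[match(design$replicate, reps)]
      }
      if (noise_sd[j] > 0) y <- y + stats::rnorm(length(y), 0, noise_sd[j])
      design[[resp]] <- pmax(y, 0)
    }
    design
  })
}

#' Simulate a complete synthetic elicitation experiment
#'
#' Convenience wrapper: [generate_design()] then [simulate_responses()].
#'
#' @inheritParams generate_design
#' @inheritParams simulate_responses
#' @export
simulate_experiment <- function(config = design_config(),
                                params = surface_params(),
                                seed = params$seed) {
  simulate_responses(generate_design(config), params, seed)
}

#' Locate the true optimum of a noiseless surface by dense grid search
#'
#' Oracle used to validate surrogate-based optimization: exhaustively
#' evaluates [true_response()] on a regular grid over the given box, keeping
#' only points with `harvest_day > adding_day`.
#'
#' @param params a [surface_params()].
#' @param bounds named list of `c(lower, upper)` intervals for `ce_conc`,
#'   `cf_conc`, `adding_day`, `harvest_day`.
#' @param response response name to maximize.
#' @param grid_step grid spacing (same for all four inputs).
#' @return list with `inputs` (named numeric vector), `value`, `grid_step`.
#' @export
true_optimum <- function(params,
                         bounds = list(ce_conc = c(0, 10), cf_conc = c(0, 10),
                                       adding_day = c(13, 17),
                                       harvest_day = c(13, 23)),
                         response = "total", grid_step = 0.25) {
  response <- match.arg(response, TABLE_RESPONSES)
  check_number(grid_step, "grid_step", lower = 1e-6)
  axes <- lapply(bounds[TABLE_INPUTS], function(b) seq(b[1], b[2], by = grid_step))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$harvest_day > grid$adding_day, , drop = FALSE]
  if (nrow(grid) == 0L) stopf("no feasible grid point (harvest > adding)")
  val <- true_response(params, grid$ce_conc, grid$cf_conc,
                       grid$adding_day, grid$harvest_day, response)
  i <- which.max(val)
  list(inputs = unlist(grid[i, TABLE_INPUTS]), value = val[i],
       grid_step = grid_step)
}
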