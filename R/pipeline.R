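# End-to-end orchestration: simulate (or ingest) traces, segment them into
# dwells, fit the dwell-time distributions, derive microscopic rate
# constants, and optionally fit condition dependences; every artifact is
# linked to its inputs, parameters and seed in a run manifest.

default_run_config <- function() {
  list(
    seed = 1L,
    rates = list(k1 = 0.1, k_neg1 = 1.7, k2 = 0.16,
                 k3 = 0.0525, k_neg3 = 0.0389, k5 = 0.0385,
                 R_conc = 5),
    n_traces = 4L,
    duration = 1500,
    z_CS = 900, jump_pos = 73, jump_neg = 42, supercoiling_sign = "+",
    noise_sd = 25, f_s = 58, decimate = 10, drift_rate = 0,
    penalty = 1.0, min_size = 2L, t_min = 0.09,
    restarts = 8L, n_boot = 200L, boot_restarts = 2L,
    save_traces = FALSE
  )
}

#' Run the full dwell-kinetics pipeline
#'
#' Executes simulate (or ingests user traces), segment, dwell fitting with
#' BIC model selection and bootstrap errors, and microscopic-rate
#' derivation with error propagation; writes dwell tables, fit JSONs and a
#' manifest into `out_dir`. All randomness derives from `config$seed`
#' (per-stage offsets), so a rerun with the same config is reproducible.
#'
#' @param config Named list of stage parameters (see
#'   `opendwell:::default_run_config()` for the keys and defaults); or a
#'   path readable by [read_run_config()]. Supplying `trace_files`
#'   (paths of [write_trace()]-format TSVs) skips simulation.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the results list (also serialized under `out_dir`):
#'   `dwells`, `cs_fit`, `os_fit`, `derived`, `k_open`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("odrun")) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rates <- as_rate_constants(cfg$rates)
  manifest <- list(seed = cfg$seed, config = cfg, stages = list())
  stage_files <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_json_result(manifest, file.path(out_dir, "manifest.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- stage 1: simulate or ingest -----------------------------------------
  f_eff <- cfg$f_s / cfg$decimate
  traces <- run_stage("simulate", {
    if (!is.null(cfg$trace_files)) {
      lapply(cfg$trace_files, read_trace)
    } else {
      lapply(seq_len(cfg$n_traces), function(i) {
        traj <- simulate_trajectory(rates, cfg$duration,
                                    seed = cfg$seed + 1000L + i)
        tc <- trace_config(rates, z_CS = cfg$z_CS, jump_pos = cfg$jump_pos,
                           jump_neg = cfg$jump_neg,
                           supercoiling_sign = cfg$supercoiling_sign,
                           noise_sd = cfg$noise_sd, f_s = cfg$f_s,
                           duration = cfg$duration, decimate = cfg$decimate,
                           drift_rate = cfg$drift_rate,
                           seed = cfg$seed + 2000L + i)
        tr <- render_trace(traj, tc)
        if (isTRUE(cfg$save_traces)) {
          p <- file.path(out_dir, sprintf("trace_%03d.tsv", i))
          write_trace(tr, p)
          stage_files <<- c(stage_files, p)
        }
        tr
      })
    }
  })
  manifest$stages$simulate <- list(
    status = "ok", n_traces = length(traces),
    source = if (is.null(cfg$trace_files)) "simulated" else "ingested",
    seeds = if (is.null(cfg$trace_files))
      cfg$seed + 1000L + seq_along(traces) else NULL,
    files = stage_files)

  # -- stage 2: segment ----------------------------------------------------
  dwells <- run_stage("segment", {
    dws <- lapply(traces, function(tr) {
      z <- detrend_extension(tr$t, tr$z)
      bp <- detect_changepoints(z, penalty = cfg$penalty,
                                min_size = cfg$min_size)
      seg <- label_segments(z, bp)
      extract_dwells(seg, f_s_eff = f_eff, t_min = cfg$t_min)
    })
    pooled <- do.call(rbind, lapply(dws, as.data.frame))
    as_dwell_set(pooled, t_min = cfg$t_min)
  })
  dwell_path <- file.path(out_dir, "dwells.tsv")
  write_dwells(dwells, dwell_path)
  manifest$stages$segment <- list(
    status = "ok", penalty = cfg$penalty, min_size = cfg$min_size,
    t_min = cfg$t_min, n_dwells = nrow(dwells),
    n_os = sum(dwells$label == "OS" & !dwells$censored),
    n_cs = sum(dwells$label == "CS" & !dwells$censored),
    files = dwell_path)

  # -- stage 3: dwell-distribution fits ------------------------------------
  fits <- run_stage("fit_dwells", {
    set.seed(cfg$seed + 3000L)
    cs <- fit_dwell_distribution(dwells, label = "CS", t_min = cfg$t_min,
                                 restarts = cfg$restarts,
                                 n_boot = cfg$n_boot,
                                 boot_restarts = cfg$boot_restarts)
    os <- fit_dwell_distribution(dwells, label = "OS", t_min = cfg$t_min,
                                 restarts = cfg$restarts,
                                 n_boot = cfg$n_boot,
                                 boot_restarts = cfg$boot_restarts)
    list(cs = cs, os = os)
  })
  fit_path <- file.path(out_dir, "dwell_fits.json")
  write_json_result(list(
    CS = fits$cs[c("model", "params", "sds", "logL", "bic", "n", "n_boot",
                   "t_min")],
    OS = fits$os[c("model", "params", "sds", "logL", "bic", "n", "n_boot",
                   "t_min")],
    seed = cfg$seed), fit_path)
  manifest$stages$fit_dwells <- list(
    status = "ok", cs_model = fits$cs$model, os_model = fits$os$model,
    n_boot = cfg$n_boot, files = fit_path)

  # -- stage 4: microscopic rates ------------------------------------------
  derived <- run_stage("derive_rates", {
    k_open <- list(value = fits$cs$params$k,
                   sd = if (!is.null(fits$cs$sds)) fits$cs$sds$k else NA)
    der <- NULL
    if (fits$os$model == "double") {
      emp <- exp_mix_params(fits$os$params$k_plus, fits$os$params$k_minus,
                            fits$os$params$p_minus)
      der <- if (!is.null(fits$os$sds)) {
        propagate_errors(emp, c(k_plus = fits$os$sds$k_plus,
                                k_minus = fits$os$sds$k_minus,
                                p_minus = fits$os$sds$p_minus))
      } else fit_to_micro(emp)
    }
    list(k_open = k_open, micro = der)
  })
  der_path <- file.path(out_dir, "derived_rates.json")
  write_json_result(list(k_open = derived$k_open,
                         micro = if (!is.null(derived$micro))
                           unclass(derived$micro),
                         seed = cfg$seed), der_path)
  manifest$stages$derive_rates <- list(status = "ok", files = der_path)

  # -- stage 5: condition-dependence fits (optional tables) ----------------
  dep <- run_stage("dependence_fits", {
    out <- list()
    if (!is.null(cfg$binding_table)) {
      tb <- utils::read.table(cfg$binding_table, header = TRUE,
                              sep = "\t", comment.char = "#")
      out$binding <- fit_binding(tb[[1]], tb[[2]],
                                 sd = if (ncol(tb) > 2) tb[[3]])
    }
    if (!is.null(cfg$temperature_table)) {
      tb <- utils::read.table(cfg$temperature_table, header = TRUE,
                              sep = "\t", comment.char = "#")
      out$temperature <- fit_kopen_temperature(tb[[2]], tb[[1]],
                                               R_conc = rates$R_conc)
    }
    if (!is.null(cfg$salt_table)) {
      tb <- utils::read.table(cfg$salt_table, header = TRUE,
                              sep = "\t", comment.char = "#")
      out$salt <- salt_sensitivity(tb[[2]], tb[[1]])
    }
    out
  })
  manifest$stages$dependence_fits <- list(
    status = "ok", fitted = names(dep))

  write_json_result(manifest, file.path(out_dir, "manifest.json"))
  res <- list(dwells = dwells, cs_fit = fits$cs, os_fit = fits$os,
              k_open = derived$k_open, derived = derived$micro,
              dependence = dep, manifest = manifest, out_dir = out_dir)
  invisible(res)
}

#' Generate the canonical synthetic fixture set
#'
#' Writes, under `dir`:
#' \describe{
#'   \item{trace_a.tsv / dwells_a.tsv}{A single-condition trace bundle at
#'     the default (150 mM KAc-like) rates with its ground-truth dwells.}
#'   \item{binding_series.tsv}{Opening rates over 0.2-10 nM holo from the
#'     hyperbolic binding curve (K_D = 17 nM, k2 = 0.16 1/s) with
#'     multiplicative noise.}
#'   \item{temperature_series.tsv}{Opening rates over 25-45 C from the
#'     coupled binding-Arrhenius form (dE2 = 22, dE_diff = 107 kcal/mol),
#'     non-monotonic with an interior maximum.}
#'   \item{salt_series.tsv}{Power-law opening rates over 50-300 mM salt
#'     with sensitivity S = -2.3.}
#'   \item{rotation_ref.tsv / rotation_test.tsv}{A rotation-extension
#'     curve pair with a programmed +7.7 turn apex shift on a 20.6 kb
#'     tether, 5 nm extension noise.}
#' }
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param noise Relative noise on the rate series (default 2%, the
#'   standard error of a rate estimated from roughly 2000 dwells).
#' @return Named list of file paths, with the programmed ground truth as
#'   attribute `truth`.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("odfix"), noise = 0.02) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- list()
  truth <- list()

  # (a) single-condition trace bundle
  rates <- rate_constants(k1 = 0.1, k_neg1 = 1.7, k2 = 0.16,
                          k3 = 0.0525, k_neg3 = 0.0389, k5 = 0.0385,
                          R_conc = 5)
  traj <- simulate_trajectory(rates, duration = 1500, seed = seed + 11L)
  tc <- trace_config(rates, duration = 1500, seed = seed + 12L,
                     label = list(salt = "150 mM KAc", temp_C = 34))
  tr <- render_trace(traj, tc)
  files$trace_a <- file.path(dir, "trace_a.tsv")
  write_trace(tr, files$trace_a)
  files$dwells_a <- file.path(dir, "dwells_a.tsv")
  write_dwells(true_dwells(traj), files$dwells_a)
  truth$rates <- rates

  # (b) holo-concentration series
  KD <- 17; k2 <- 0.16
  Rc <- c(0.2, 0.5, 1, 2, 5, 10)
  k_open <- k2 * Rc / (KD + Rc) * exp(stats::rnorm(length(Rc), sd = noise))
  files$binding_series <- file.path(dir, "binding_series.tsv")
  utils::write.table(
    data.frame(R_conc_nM = Rc, k_open_s = k_open,
               sd_s = noise * k_open),
    files$binding_series, sep = "\t", row.names = FALSE, quote = FALSE)
  truth$binding <- list(K_D = KD, k2 = k2)

  # (c) temperature series (non-monotonic opening rate)
  dE2 <- 22; dEd <- 107; R5 <- 5
  TC <- c(25, 30, 34, 37, 41, 45)
  TK <- TC + 273.15
  T0 <- 273.15 + 34
  k2T <- 0.16 * exp(-dE2 / R_GAS_KCAL * (1 / TK - 1 / T0))
  KDT <- 17 * exp(-dEd / R_GAS_KCAL * (1 / TK - 1 / T0))
  kT <- k2T * R5 / (KDT + R5) * exp(stats::rnorm(length(TC), sd = noise))
  files$temperature_series <- file.path(dir, "temperature_series.tsv")
  utils::write.table(
    data.frame(temp_C = TC, k_open_s = kT, sd_s = noise * kT),
    files$temperature_series, sep = "\t", row.names = FALSE, quote = FALSE)
  truth$temperature <- list(dE2 = dE2, dE_diff = dEd, R_conc = R5,
                            k2_34C = 0.16, KD_34C = 17)

  # (d) salt series (power law)
  S <- -2.3
  salt <- c(50, 75, 100, 150, 200, 300)
  ks <- 0.2 * (salt / 100)^S * exp(stats::rnorm(length(salt), sd = noise))
  files$salt_series <- file.path(dir, "salt_series.tsv")
  utils::write.table(
    data.frame(salt_mM = salt, k_open_s = ks, sd_s = noise * ks),
    files$salt_series, sep = "\t", row.names = FALSE, quote = FALSE)
  truth$salt <- list(S = S)

  # (e) rotation-curve pair with programmed twist shift
  shift <- 7.7; kb <- 20.6
  turns <- seq(-70, 70, by = 1)
  hat <- function(x, center) {
    w <- 8; s <- 60; e0 <- 5500
    d <- abs(x - center)
    ifelse(d <= w, e0 - s / (2 * w) * d^2, e0 - s * w / 2 - s * (d - w))
  }
  ref <- data.frame(turns = turns,
                    ext = hat(turns, 0) + stats::rnorm(length(turns), sd = 5))
  tst <- data.frame(turns = turns,
                    ext = hat(turns, shift) +
                      stats::rnorm(length(turns), sd = 5))
  files$rotation_ref <- file.path(dir, "rotation_ref.tsv")
  files$rotation_test <- file.path(dir, "rotation_test.tsv")
  utils::write.table(ref, files$rotation_ref, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(tst, files$rotation_test, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth$rotation <- list(shift_turns = shift, length_kb = kb)

  attr(files, "truth") <- truth
  files
}
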