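# Experiment orchestration: validated plans, composite runs, file output.
#
# Arrays and tidy statistics are written as plain CSV, summaries and config
# echoes as JSON; every output carries the full configuration and seed so a
# re-run of the same plan reproduces the files byte for byte.

#' Experiment plan
#'
#' @param experiment one of `"kernels_verify"`, `"rate"`, `"clt"`, `"lln"`,
#'   `"couple"`, `"pde_only"`.
#' @param config a [sim_config()].
#' @param diagnostics list of experiment-specific settings: `N_list`,
#'   `replicas`, `alpha` (coupling exponent), `theta` (LLN exponent),
#'   `tf` (a [test_function()]).
#' @param output_dir directory for result files (created if missing).
#' @return an object of class `"experiment_plan"`.
#' @export
experiment_plan <- function(experiment, config, diagnostics = list(),
                            output_dir = tempfile("modfluct_")) {
  experiment <- match.arg(experiment, c("kernels_verify", "rate", "clt",
                                        "lln", "couple", "pde_only"))
  structure(list(experiment = experiment, config = config,
                 diagnostics = diagnostics, output_dir = output_dir),
            class = "experiment_plan")
}

#' Validate an experiment plan
#'
#' Aggregates all parameter-range violations into one readable error:
#' `d >= 3`, the sub-Coulomb window for `lambda`, `sigma > 0` outside test
#' modes, the admissible `beta` range for rate runs
#' (`beta < 1/(8 lambda + 12)`), the admissible coupling window for `alpha`
#' (`beta(lambda+3) < alpha < 1/2 - beta(lambda+1)`), the LLN window for
#' `theta`, mollifier resolution (`2 eta >= 4 h`), and at least three `N`
#' values for a rate fit.
#'
#' @param plan an [experiment_plan()].
#' @return the validated plan, invisibly; stops with the collected
#'   violations otherwise.
#' @export
validate_config <- function(plan) {
  cfg <- plan$config
  dg <- plan$diagnostics
  errs <- character()
  collect <- function(e) errs <<- c(errs, conditionMessage(e))
  tryCatch(check_sim_config(cfg), error = collect)
  if (2 * cfg$eta < 4 * cfg$L / cfg$n) {
    errs <- c(errs, sprintf("mollifier support 2*eta = %.4g spans fewer than 4 cells (h = %.4g)",
                            2 * cfg$eta, cfg$L / cfg$n))
  }
  if (plan$experiment == "rate") {
    if (!(cfg$beta < 1 / (8 * cfg$lambda + 12))) {
      errs <- c(errs, sprintf("rate run requires beta < 1/(8 lambda + 12) = %g, got %g",
                              1 / (8 * cfg$lambda + 12), cfg$beta))
    }
    if (is.null(dg$N_list) || length(dg$N_list) < 3) {
      errs <- c(errs, "rate run requires N_list with at least 3 values")
    }
  }
  if (plan$experiment == "couple") {
    lo <- cfg$beta * (cfg$lambda + 3)
    hi <- 0.5 - cfg$beta * (cfg$lambda + 1)
    if (is.null(dg$alpha) || !(dg$alpha > lo && dg$alpha < hi)) {
      errs <- c(errs, sprintf("coupling run requires alpha in (%g, %g)", lo, hi))
    }
  }
  if (plan$experiment == "lln") {
    hi <- 0.5 - cfg$beta * (cfg$lambda + 1)
    if (is.null(dg$theta) || dg$theta < 0 || dg$theta >= hi) {
      errs <- c(errs, sprintf("lln run requires theta in [0, %g)", hi))
    }
  }
  if (length(errs)) {
    stop(paste0("invalid experiment plan:\n  - ",
                paste(errs, collapse = "\n  - ")))
  }
  invisible(plan)
}

run_log <- function(plan, what) {
  message(sprintf("[modfluct:%s] %s", plan$experiment, what))
}

#' Run an experiment plan
#'
#' Validates the plan, executes the module pipeline for the chosen
#' experiment, and writes tidy CSV tables plus a JSON summary (with the full
#' config echo and seed) to the output directory. Re-running the same plan
#' reproduces the files byte for byte.
#'
#' @param plan an [experiment_plan()].
#' @return the result object of the underlying computation, invisibly.
#' @export
run_experiment <- function(plan) {
  validate_config(plan)
  dir.create(plan$output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- plan$config
  dg <- plan$diagnostics
  res <- switch(plan$experiment,
    kernels_verify = {
      run_log(plan, "kernel factorization and growth checks")
      grid <- torus_grid(cfg$n, cfg$d, cfg$L)
      spec <- riesz_spec(cfg$d, cfg$lambda)
      tab <- build_kernel_tables(spec, mollifier_spec(cfg$eta, cfg$beta), grid)
      nz <- tab$Phi_symbol > 0
      fac_err <- max(abs(tab$V_eta_symbol[nz] - tab$Z_eta_symbol[nz]^2)) /
        max(abs(tab$V_eta_symbol))
      rep <- kernel_scaling_report(spec, cfg$beta,
                                   dg$N_list %||% c(1e3, 1e4, 1e5))
      utils::write.csv(rep, file.path(plan$output_dir, "scaling_report.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(r = tab$r_grid, V = tab$V_eta,
                                  dV = tab$dV_eta),
                       file.path(plan$output_dir, "kernel_tables.csv"),
                       row.names = FALSE)
      list(factorization_error = fac_err, scaling = rep)
    },
    rate = {
      run_log(plan, sprintf("rate fit over N in {%s}",
                            paste(dg$N_list, collapse = ", ")))
      fit <- estimate_rate(cfg, dg$N_list, dg$replicas %||% 8)
      df <- data.frame(N = rep(fit$N_list, each = fit$replicas),
                       replica = rep(seq_len(fit$replicas),
                                     times = length(fit$N_list)),
                       sup_l2_sq = unlist(fit$per_replica))
      utils::write.csv(df, file.path(plan$output_dir, "rate_replicas.csv"),
                       row.names = FALSE)
      fit
    },
    clt = {
      run_log(plan, "dynamic CLT experiment")
      tf <- dg$tf %||% test_function("gaussian_bump", rep(0, cfg$d))
      out <- fluctuation_experiment(cfg, tf, dg$replicas %||% 100)
      utils::write.csv(data.frame(replica = seq_along(out$samples),
                                  pairing = out$samples),
                       file.path(plan$output_dir, "clt_samples.csv"),
                       row.names = FALSE)
      out
    },
    lln = {
      run_log(plan, "law-of-large-numbers diagnostic")
      out <- lln_probability(cfg, dg$theta, dg$replicas %||% 20)
      utils::write.csv(data.frame(replica = seq_along(out$max_dev),
                                  max_dev = out$max_dev,
                                  threshold = out$threshold),
                       file.path(plan$output_dir, "lln_replicas.csv"),
                       row.names = FALSE)
      out
    },
    couple = {
      run_log(plan, "shared-noise coupling diagnostic")
      out <- coupling_probability(cfg, dg$alpha, dg$replicas %||% 12)
      utils::write.csv(data.frame(replica = seq_along(out$sup_coupling),
                                  sup_coupling = out$sup_coupling,
                                  threshold = out$threshold),
                       file.path(plan$output_dir, "couple_replicas.csv"),
                       row.names = FALSE)
      out
    },
    pde_only = {
      run_log(plan, "intermediate equation solve")
      grid <- torus_grid(cfg$n, cfg$d, cfg$L)
      spec <- riesz_spec(cfg$d, cfg$lambda)
      tab <- build_kernel_tables(spec, mollifier_spec(cfg$eta, cfg$beta), grid)
      u0 <- gaussian_field(grid, cfg$s0, cfg$center)
      sol <- solve_forward(u0, tab$V_eta_symbol, cfg$sigma, cfg$kappa,
                           cfg$dt, cfg$T, save_stride = cfg$snapshot_stride)
      utils::write.csv(data.frame(t = sol$times, mass = sol$mass_series,
                                  min_u = sol$min_series),
                       file.path(plan$output_dir, "pde_mass.csv"),
                       row.names = FALSE)
      sol
    })
  summary <- list(experiment = plan$experiment,
                  config = unclass(cfg)[!vapply(unclass(cfg), is.function,
                                                logical(1))],
                  diagnostics = dg[!vapply(dg, is.object, logical(1))],
                  headline = result_headline(res))
  jsonlite::write_json(summary, file.path(plan$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(plan, sprintf("results written to %s", plan$output_dir))
  invisible(res)
}

result_headline <- function(res) {
  if (inherits(res, "rate_fit")) {
    list(slope = res$slope, slope_se = res$slope_se)
  } else if (inherits(res, "clt_test")) {
    list(variance_ratio = res$variance_ratio, ks_pvalue = res$ks_pvalue)
  } else if (inherits(res, "pde_solution")) {
    list(mass_drift = diff(range(res$mass_series)), blowup = res$blowup)
  } else if (is.list(res) && !is.null(res$prob)) {
    list(prob = res$prob, threshold = res$threshold)
  } else if (is.list(res) && !is.null(res$factorization_error)) {
    list(factorization_error = res$factorization_error)
  } else NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
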