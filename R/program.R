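#' Configuration of a recurrent-selection program
#'
#' Collects and validates the knobs of the forward-in-time simulation: a
#' base population of inbred lines is phenotyped, 70% of lines train the
#' genomic prediction model, the remaining 30% are the selection candidates,
#' the top `q` of candidates (by minimum posterior expected loss, or by
#' highest posterior-mean breeding value for `"Std"`) are intermated to
#' recover the population size, for `cycles` cycles and `replicates`
#' replicate programs.
#'
#' The asymmetry parameter defaults follow the pressure: `alpha` (LinLin)
#' and the per-trait `tau` (MALF) are 0.9 under 10% selection and 0.7 under
#' 30% selection.
#'
#' @param n Founder population size (default 500).
#' @param p Number of loci (default 1000).
#' @param h2 Target heritability, one value or one per trait (default 0.5).
#' @param traits Number of traits: 1 (BRR prediction) or more (multi-trait
#'   model).
#' @param cor_targets Genetic-correlation targets for `traits > 1`.
#' @param cycles Number of selection cycles (default 10).
#' @param q Selection pressure on the candidate set (default 0.10).
#' @param criterion `"KL"`, `"CRPS"`, `"LinLin"`, `"EnergyS"`, `"Std"`
#'   (univariate) or `"mKL"`, `"EnergyS"`, `"MALF"` (multivariate).
#' @param train_frac Training fraction per cycle (default 0.70).
#' @param replicates Number of replicate programs (default 20).
#' @param alpha,tau Asymmetry parameters; `NULL` picks the pressure default.
#' @param mcmc Chain settings from [mcmc_settings()] (default fast profile).
#' @param effect_signs Sign rule for univariate gamma effects.
#' @param recalibrate Recalibrate residual variance each cycle.
#' @param seed Master seed; replicate seeds derive deterministically from it.
#' @return A validated list of class `"program_config"`.
#' @export
program_config <- function(n = 500, p = 1000, h2 = 0.5, traits = 1,
                           cor_targets = default_cor_targets(),
                           cycles = 10, q = 0.10, criterion = "KL",
                           train_frac = 0.70, replicates = 20,
                           alpha = NULL, tau = NULL,
                           mcmc = mcmc_settings("fast"),
                           effect_signs = "random",
                           recalibrate = FALSE, seed = 1L) {
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)")
  if (train_frac <= 0 || train_frac >= 1) stop("`train_frac` must lie in (0, 1)")
  if (cycles < 1 || replicates < 1) stop("`cycles` and `replicates` must be positive")
  uni <- c("KL", "CRPS", "LinLin", "EnergyS", "Std")
  mv <- c("mKL", "EnergyS", "MALF")
  if (traits == 1) {
    if (!criterion %in% uni) stop("univariate criterion must be one of: ", paste(uni, collapse = ", "))
  } else {
    if (!criterion %in% mv) stop("multivariate criterion must be one of: ", paste(mv, collapse = ", "))
  }
  asym_default <- if (q <= 0.2) 0.9 else 0.7
  if (is.null(alpha)) alpha <- asym_default
  if (is.null(tau)) tau <- rep(asym_default, traits)
  if (length(h2) == 1) h2 <- rep(h2, traits)
  structure(
    list(n = n, p = p, h2 = h2, traits = traits, cor_targets = cor_targets,
         cycles = cycles, q = q, criterion = criterion,
         train_frac = train_frac, replicates = replicates,
         alpha = alpha, tau = tau, mcmc = mcmc,
         effect_signs = effect_signs, recalibrate = recalibrate,
         seed = as.integer(seed)),
    class = "program_config"
  )
}

# breeding-value draws for all lines of the current population under an MTM
# fit on the training subset: training lines read off the chain, candidates
# conditioned on them through K
.mtm_bv_all <- function(fit, K, train, cand, type = "bv") {
  n <- nrow(K); t_tr <- fit$t; m <- nrow(fit$m)
  out <- array(0, c(n, t_tr, m))
  for (j in seq_len(m)) {
    out[train, , j] <- sweep(matrix(fit$U[, , j], ncol = t_tr), 2, fit$m[j, ], `+`)
  }
  out[cand, , ] <- predictive_draws(fit, K, train, cand, type = "bv")
  if (type == "phenotype") {
    for (j in seq_len(m)) {
      Rj <- matrix(fit$Rcov[, , j], t_tr, t_tr)
      out[, , j] <- out[, , j] + matrix(stats::rnorm(n * t_tr), n, t_tr) %*% chol(Rj)
    }
  }
  dimnames(out) <- list(rownames(K), fit$trait_names, NULL)
  out
}

# one cycle: phenotype, fit, rank, select, cross; returns next genotypes and ids
.run_cycle <- function(X, arch, config) {
  pop <- simulate_phenotypes(X, arch, recalibrate = config$recalibrate)
  n <- nrow(X)
  n_train <- round(config$train_frac * n)
  train <- sort(sample.int(n, n_train))
  cand <- setdiff(seq_len(n), train)
  sel_ids <- if (config$traits == 1) {
    y <- pop$phenotypes[, 1]
    fit <- fit_brr(y[train], X[train, , drop = FALSE], mcmc = config$mcmc)
    bv_all <- predictive_draws(fit, X)
    bv_cand <- bv_all[cand, , drop = FALSE]
    if (config$criterion == "Std") {
      std_selection(bv_cand, config$q)$selected
    } else {
      yo <- if (config$criterion == "EnergyS") {
        predictive_draws(fit, X[cand, , drop = FALSE], type = "phenotype")
      } else NULL
      tbl <- expected_loss_univariate(bv_all, bv_cand, fit$sigma2_e, config$q,
                                      criterion = config$criterion,
                                      alpha = config$alpha, yo_cand = yo)
      select_top(rank_candidates(tbl), config$q)$selected
    }
  } else {
    K <- grm(X)
    fit <- fit_mtm(pop$phenotypes[train, , drop = FALSE],
                   K[train, train, drop = FALSE], mcmc = config$mcmc)
    bv_all <- .mtm_bv_all(fit, K, train, cand)
    bv_cand <- bv_all[cand, , , drop = FALSE]
    yo <- if (config$criterion == "EnergyS") {
      predictive_draws(fit, K, train, cand, type = "phenotype")
    } else NULL
    tbl <- expected_loss_multivariate(bv_all, bv_cand, fit$Rcov, config$q,
                                      criterion = config$criterion,
                                      tau = config$tau, yo_cand = yo)
    select_top(rank_candidates(tbl), config$q)$selected
  }
  parents <- X[sel_ids, , drop = FALSE]
  list(pop = pop, offspring = make_crosses(parents, n), selected = sel_ids)
}

#' Run a recurrent genomic-selection program
#'
#' Executes the configured number of replicate programs, each a fully
#' seeded chain of cycles: phenotype the population, fit the prediction
#' model on a 70% training split, score the 30% candidate split by
#' posterior expected loss (or posterior-mean breeding value for `"Std"`),
#' select the top `q`, and intermate the selected parents to recover the
#' population size. Population summaries are recorded each cycle *before*
#' selection.
#'
#' @param config A [program_config()].
#' @return An object of class `"breeding_program"`: list with `records`
#'   (long data.frame: replicate, cycle, trait, mean_tbv, var_tbv,
#'   mean_pheno, var_pheno, std_response, scaled_var) and `config`.
#'   Standardized response `(mu_i - mu_1)/sigma_1` and scaled variance
#'   `sigma_i^2/sigma_1^2` are on the true-breeding-value scale, relative
#'   to each replicate's first cycle.
#' @export
run_program <- function(config) {
  stopifnot(inherits(config, "program_config"))
  recs <- list()
  for (r in seq_len(config$replicates)) {
    rep_seed <- (config$seed + 104729 * r) %% 2147483647L
    set.seed(rep_seed)
    X <- simulate_founders(config$n, config$p)
    B <- if (config$traits == 1) {
      sample_effects_univariate(config$p, signs = config$effect_signs)
    } else {
      sample_effects_multitrait(config$p, cor_targets = config$cor_targets)
    }
    arch <- trait_architecture(B, config$h2, X)
    for (cyc in seq_len(config$cycles)) {
      step <- .run_cycle(X, arch, config)
      tbv <- step$pop$tbv; phe <- step$pop$phenotypes
      recs[[length(recs) + 1L]] <- data.frame(
        replicate = r, cycle = cyc, trait = seq_len(config$traits),
        mean_tbv = colMeans(tbv), var_tbv = apply(tbv, 2, stats::var),
        mean_pheno = colMeans(phe), var_pheno = apply(phe, 2, stats::var)
      )
      X <- step$offspring
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  records$std_response <- NA_real_
  records$scaled_var <- NA_real_
  for (r in unique(records$replicate)) {
    for (k in unique(records$trait)) {
      sel <- records$replicate == r & records$trait == k
      base <- records[sel & records$cycle == 1, ]
      records$std_response[sel] <-
        (records$mean_tbv[sel] - base$mean_tbv) / sqrt(base$var_tbv)
      records$scaled_var[sel] <- records$var_tbv[sel] / base$var_tbv
    }
  }
  structure(list(records = records, config = config), class = "breeding_program")
}

#' @export
print.breeding_program <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Recurrent-selection program: %d replicates x %d cycles, %s, q = %.2f\n",
              cfg$replicates, cfg$cycles, cfg$criterion, cfg$q))
  s <- summarize_program(x)
  print(utils::tail(s$trajectory, cfg$traits))
  invisible(x)
}

#' Summarize a simulated breeding program across replicates
#'
#' Replicate means and standard errors of the standardized response and the
#' scaled genetic variance per cycle and trait, plus the percent change of
#' the genetic mean and variance between the last and the first cycle:
#' `100 * (v_last - v_1) / v_1`, averaged across replicates.
#'
#' @param x A `"breeding_program"` or its `records` data.frame.
#' @return A list with `trajectory` (cycle x trait summary) and
#'   `percent_change` (per trait and quantity, with standard errors; the
#'   SE is `NA` for a single replicate).
#' @export
summarize_program <- function(x) {
  records <- if (inherits(x, "breeding_program")) x$records else x
  req <- c("replicate", "cycle", "trait", "mean_tbv", "var_tbv")
  if (!all(req %in% names(records))) stop("records are missing required columns")
  if (max(records$cycle) < 2) stop("at least two cycles are required to summarize")
  se <- function(v) if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  traj <- do.call(rbind, lapply(split(records, records[c("cycle", "trait")]), function(d) {
    data.frame(cycle = d$cycle[1], trait = d$trait[1],
               std_response = mean(d$std_response), se_response = se(d$std_response),
               scaled_var = mean(d$scaled_var), se_scaled_var = se(d$scaled_var))
  }))
  traj <- traj[order(traj$trait, traj$cycle), ]
  rownames(traj) <- NULL
  last <- max(records$cycle)
  pc <- do.call(rbind, lapply(split(records, records$trait), function(d) {
    out <- lapply(c(mean = "mean_tbv", variance = "var_tbv"), function(col) {
      v1 <- d[[col]][d$cycle == 1]
      vL <- d[[col]][d$cycle == last]
      if (any(v1 == 0)) stop("percent change undefined: first-cycle value is zero")
      pd <- 100 * (vL - v1) / v1
      c(mean(pd), se(pd))
    })
    data.frame(trait = d$trait[1], quantity = names(out),
               percent_change = vapply(out, `[`, 0, 1),
               se = vapply(out, `[`, 0, 2))
  }))
  rownames(pc) <- NULL
  list(trajectory = traj, percent_change = pc)
}
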