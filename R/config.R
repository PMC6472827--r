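#' Run configuration
#'
#' Analyses are specified by a small human-writable YAML file with five
#' blocks: `data` (alignment path and tip-date convention), `site`
#' (substitution model or model-averaging settings), `clock`, `prior` (tree
#' prior and which scalar parameters to estimate), `chain`, and `output`.
#' Unknown keys anywhere are rejected and every schema violation is
#' reported, not only the first.
#'
#' @name run_config
NULL

config_schema <- function() {
  list(
    data = list(alignment = NULL, format = "fasta", date_sep = NULL,
                date_table = NULL, date_direction = "forward"),
    site = list(code = "111111", model_averaging = FALSE,
                model_set = "no_ti_tv_sharing", freqs_equal = TRUE,
                use_gamma = FALSE, gamma_categories = 4L, gamma_shape = 1,
                use_inv = FALSE, p_inv = 0),
    clock = list(kind = "strict", mean_rate = 1, sigma = 0,
                 n_categories = 20L),
    prior = list(tree = "coalescent", Ne = 1, lambda = 1, mu = 0, psi = 0,
                 r = 1, rho = 0, t0 = NULL, change_times = list(),
                 estimate = list()),
    chain = list(length = 10000L, log_every = 100L, seed = 1L),
    output = list(prefix = "phylomc"))
}

#' Load and validate a run configuration
#'
#' @param path YAML file path
#' @return validated configuration list with defaults filled in
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  errors <- character(0)
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top))
    errors <- c(errors, paste0("unknown block: ", unknown_top))
  out <- schema
  for (blk in intersect(names(cfg), names(schema))) {
    unknown <- setdiff(names(cfg[[blk]]), names(schema[[blk]]))
    if (length(unknown))
      errors <- c(errors, paste0("unknown key: ", blk, ".", unknown))
    for (key in intersect(names(cfg[[blk]]), names(schema[[blk]])))
      if (!is.null(cfg[[blk]][[key]]))    # NULL in YAML means "use default"
        out[[blk]][[key]] <- cfg[[blk]][[key]]
  }
  ## value checks
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(out$data$format %in% c("fasta", "nexus"), "data.format must be fasta or nexus")
  chk(out$clock$kind %in% c("strict", "relaxed_lognormal"),
      "clock.kind must be strict or relaxed_lognormal")
  chk(out$prior$tree %in% c("coalescent", "bd_serial", "bdsky"),
      "prior.tree must be coalescent, bd_serial or bdsky")
  chk(out$site$model_set %in% c("all_reversible", "no_ti_tv_sharing"),
      "site.model_set must be all_reversible or no_ti_tv_sharing")
  chk(out$chain$length >= 1, "chain.length must be positive")
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  out
}

#' Serialize a configuration back to YAML
#'
#' Round-trips with [load_config()]: dumping and re-loading yields an
#' identical configuration.
#'
#' @param cfg configuration list
#' @param path output file (or `NULL` to return the YAML string)
#' @export
dump_config <- function(cfg, path = NULL) {
  txt <- yaml::as.yaml(cfg)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

## assemble model objects and a posterior for a config + alignment
build_analysis <- function(cfg, aln) {
  site <- site_model(cfg$site$code, freqs_equal = cfg$site$freqs_equal,
                     use_gamma = cfg$site$use_gamma,
                     gamma_shape = cfg$site$gamma_shape,
                     n_categories = cfg$site$gamma_categories,
                     use_inv = cfg$site$use_inv, p_inv = cfg$site$p_inv)
  clock <- clock_model(cfg$clock$kind, cfg$clock$mean_rate, cfg$clock$sigma,
                       cfg$clock$n_categories)
  pat <- compress_patterns(aln)
  tips <- stats::setNames(aln$taxa$sampling_time, aln$taxa$label)
  tree0 <- simulate_coalescent_tree(tips, max(max(tips), 1))
  prior_of <- function(params) {
    pr <- utils::modifyList(cfg$prior, params)
    switch(cfg$prior$tree,
           coalescent = coalescent_params(pr$Ne),
           bd_serial = bd_params(pr$t0, pr$lambda, pr$mu, pr$psi, pr$r, pr$rho),
           bdsky = skyline_params(pr$t0, unlist(pr$change_times), pr$lambda,
                                  pr$mu, pr$psi, pr$r, pr$rho))
  }
  est <- unlist(cfg$prior$estimate)
  params <- stats::setNames(lapply(est, function(nm) cfg$prior[[nm]]), est)
  ## estimated scalars get lognormal priors centred on their initial values
  param_prior <- function(params) {
    sum(vapply(est, function(nm)
      stats::dlnorm(params[[nm]], log(cfg$prior[[nm]]), 1, log = TRUE),
      numeric(1)))
  }
  if (cfg$prior$tree == "bd_serial" && is.null(cfg$prior$t0))
    stop("bd_serial prior requires prior.t0")
  log_target <- function(state) {
    lp <- if (length(est)) param_prior(state$params) else 0
    if (!is.finite(lp)) return(-Inf)
    tp <- try(tree_prior_log_density(state$tree, prior_of(state$params)),
              silent = TRUE)
    if (inherits(tp, "try-error") || !is.finite(tp)) return(-Inf)
    lik <- log_likelihood(pat, state$tree, state$site, state$clock)
    lp + tp + lik +
      if (!is.null(state$site_set))
        site_model_log_prior(state$site, state$site_set) else 0
  }
  state0 <- list(tree = tree0, params = params, site = site, clock = clock)
  ops <- default_tree_operators(scalars = est)
  if (cfg$site$model_averaging) {
    state0$site_set <- enumerate_model_set(cfg$site$model_set)
    ops <- c(ops, list(op_rj_split_merge(state0$site_set, 8), op_rate_scale(4),
                       op_flip_indicator("use_gamma", 2),
                       op_flip_indicator("use_inv", 2),
                       op_flip_indicator("freqs_equal", 2)))
  }
  list(state0 = state0, log_target = log_target, operators = ops,
       patterns = pat, config = cfg)
}
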