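# One-command analysis pipeline: metrics -> null normalizations -> modularity
# -> rich club -> (optional) morphospace -> (optional) Kuramoto sweep,
# collected into a serialisable result bundle.

#' Pipeline configuration
#'
#' Stage toggles default to the inexpensive stages; the morphospace sampler
#' and the Kuramoto sweep dominate runtime and are opt-in. `fast = TRUE`
#' scales every stochastic stage down (hundreds of nulls, tens of runs) for
#' smoke tests.
#'
#' @param weighting weight transform applied when the input is a raw tracing
#'   table: `"log_counts"`, `"flne"`, `"flne_log"`, or `"counts"`.
#' @param n_null null-ensemble size.
#' @param n_perm permutations per permutation test.
#' @param hub_fraction rich-club hub fraction.
#' @param n_restarts modularity restarts per bisection.
#' @param run_morphospace,run_kuramoto enable the expensive stages?
#' @param morphospace settings list (`pop_size`, `n_iter`, `regimes`, `modes`).
#' @param kuramoto a [kuramoto_config].
#' @param seed integer seed for the whole pipeline.
#' @param fast scale stochastic stages down for smoke runs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(weighting = "log_counts", n_null = 1000,
                            n_perm = 1000, hub_fraction = 0.2,
                            n_restarts = 20,
                            run_morphospace = FALSE, run_kuramoto = FALSE,
                            morphospace = list(pop_size = 50, n_iter = 100,
                                               regimes = "binary_swap",
                                               modes = "max_smallworld"),
                            kuramoto = kuramoto_config(
                              lambda_grid = seq(0, 0.1, by = 0.025),
                              n_runs = 20),
                            seed = 1L, fast = FALSE) {
  cfg <- as.list(environment())
  if (fast) {
    cfg$n_null <- min(cfg$n_null, 200)
    cfg$n_perm <- min(cfg$n_perm, 200)
    cfg$morphospace$pop_size <- min(cfg$morphospace$pop_size, 20)
    cfg$morphospace$n_iter <- min(cfg$morphospace$n_iter, 20)
    cfg$kuramoto$n_runs <- min(cfg$kuramoto$n_runs, 10)
  }
  structure(cfg, class = "pipeline_config")
}

resolve_input <- function(x, config) {
  if (inherits(x, "connectome")) return(x)
  if (inherits(x, "raw_tracing"))
    return(edge_complete_subgraph(x, weighting = config$weighting))
  if (inherits(x, "synth_spec"))
    return(generate_connectome(x, seed = child_seed(config$seed, 1)))
  if (is.character(x) && length(x) == 1) return(read_connectome_csv(x))
  stopf("cannot interpret input of class %s", paste(class(x), collapse = "/"))
}

stage_msg <- function(config, stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full weighted-vs-binary connectome analysis
#'
#' Executes, in order: binary and weighted clustering and path/step lengths;
#' rewired-null normalizations and weight-shuffle comparisons; binary and
#' weighted modularity with Rand-index agreement and the intra/intermodular
#' strength contrast; rich-club curves, hub selection and connection-class
#' strength contrasts; and, when enabled, the morphospace sampler and the
#' Kuramoto coupling sweep. Every stage derives its own sub-seed from the
#' configuration seed, so two runs with the same config produce identical
#' bundles.
#'
#' @param x input: a [connectome], a [raw_tracing], a [synth_spec], or a path
#'   to a connectivity CSV.
#' @param config a [pipeline_config].
#' @return A list of class `result_bundle` with `metrics`,
#'   `null_summaries`, `partitions`, `rich_club`, `tables` (data frames ready
#'   for [write_report]), optional `morphospace` and `kuramoto` summaries,
#'   `config` and `seed`.
#' @export
run_all <- function(x, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cn <- resolve_input(x, config)
  seed <- config$seed

  stage_msg(config, "metrics", "n = %d, %d edges, seed %d", cn$n, sum(cn$A), seed)
  cb <- clustering_binary(cn)
  cw <- clustering_weighted(cn)
  lb <- path_length_binary(cn)
  lw <- path_length_weighted(cn)
  metrics <- list(
    density = network_density(cn),
    C_b = cb$network_value, C_w = cw$network_value,
    L_b = lb$network_value, L_w = lw$cost$network_value,
    Lstep_w = lw$steps$network_value
  )

  stage_msg(config, "nulls", "%d rewired + %d shuffled samples", config$n_null, config$n_null)
  rew <- null_ensemble(cn, metrics = list(
    C_b = function(z) clustering_binary(z)$network_value,
    C_w = function(z) clustering_weighted(z)$network_value,
    L_b = function(z) suppressMessages(path_length_binary(z)$network_value),
    L_w = function(z) suppressMessages(path_length_weighted(z)$cost$network_value)
  ), kind = "rewire", n_samples = config$n_null, seed = child_seed(seed, 2))
  shuf <- null_ensemble(cn, metrics = list(
    C_w = function(z) clustering_weighted(z)$network_value,
    L_w = function(z) suppressMessages(path_length_weighted(z)$cost$network_value),
    Lstep_w = function(z) suppressMessages(path_length_weighted(z)$steps$network_value)
  ), kind = "shuffle", n_samples = config$n_null, seed = child_seed(seed, 3))
  null_summaries <- list(
    C_norm_b = normalized_metric(metrics$C_b, rew, "C_b"),
    C_norm_w = normalized_metric(metrics$C_w, rew, "C_w"),
    L_norm_b = normalized_metric(metrics$L_b, rew, "L_b"),
    L_norm_w = normalized_metric(metrics$L_w, rew, "L_w"),
    C_vs_shuffled = normalized_metric(metrics$C_w, shuf, "C_w"),
    L_vs_shuffled = normalized_metric(metrics$L_w, shuf, "L_w"),
    Lstep_vs_shuffled = normalized_metric(metrics$Lstep_w, shuf, "Lstep_w")
  )

  stage_msg(config, "modularity", "%d restarts", config$n_restarts)
  part_b <- detect_modules(cn, weighted = FALSE, n_restarts = config$n_restarts,
                           seed = child_seed(seed, 4))
  part_w <- detect_modules(cn, weighted = TRUE, n_restarts = config$n_restarts,
                           seed = child_seed(seed, 5))
  ri <- rand_index(part_b, part_w, n_perm = config$n_perm,
                   seed = child_seed(seed, 6))
  ecls <- classify_edges_by_module(cn, part_b)
  w_intra <- ecls$weight[ecls$class == "intra"]
  w_inter <- ecls$weight[ecls$class == "inter"]
  intra_test <- permutation_test_groups(w_intra, w_inter, n_perm = config$n_perm,
                                        seed = child_seed(seed, 7))
  partitions <- list(
    binary = list(membership = part_b$membership, Q = part_b$Q,
                  n_modules = part_b$n_modules),
    weighted = list(membership = part_w$membership, Q = part_w$Q,
                    n_modules = part_w$n_modules),
    rand = ri,
    intra_inter_strength = list(ratio = mean(w_intra) / mean(w_inter),
                                p = intra_test$p)
  )

  stage_msg(config, "richclub", "%d nulls over k grid", config$n_null)
  rc_b <- rich_club_curve(cn, "binary", n_null = config$n_null,
                          seed = child_seed(seed, 8))
  rc_w <- rich_club_curve(cn, "weighted", n_null = config$n_null,
                          seed = child_seed(seed, 9))
  hubs <- suppressMessages(select_hubs(cn, fraction = config$hub_fraction))
  # small or oddly partitioned networks can leave a connection class empty
  # within one module scope; fall back to the overall contrast then
  contrasts <- tryCatch(
    class_strength_contrasts(cn, hubs, partition = part_b,
                             n_perm = config$n_perm,
                             seed = child_seed(seed, 10)),
    error = function(e) {
      if (!grepl("empty connection class", conditionMessage(e))) stop(e)
      stage_msg(config, "richclub",
                "module scopes dropped (%s)", conditionMessage(e))
      class_strength_contrasts(cn, hubs, n_perm = config$n_perm,
                               seed = child_seed(seed, 10))
    })
  rich_club <- list(hubs = hubs$hubs,
                    class_counts = as.list(table(hubs$edges$class)))

  tables <- list(
    rich_club_binary = rc_b$curve,
    rich_club_weighted = rc_w$curve,
    class_contrasts = contrasts,
    edge_classes = merge(ecls, hubs$edges,
                         by = c("from", "to", "weight"),
                         suffixes = c("_module", "_hub"))
  )

  morpho <- NULL
  if (isTRUE(config$run_morphospace)) {
    ms <- config$morphospace
    morpho <- list()
    for (regime in ms$regimes) for (mode in ms$modes) {
      stage_msg(config, "morphospace", "%s / %s", regime, mode)
      run <- evolve_morphospace(cn, regime = regime, mode = mode,
                                pop_size = ms$pop_size, n_iter = ms$n_iter,
                                n_null = min(config$n_null, 200),
                                seed = child_seed(seed, 11))
      key <- paste(regime, mode, sep = ".")
      morpho[[key]] <- list(
        C_norm_min = min(run$objectives$C_norm),
        C_norm_max = max(run$objectives$C_norm),
        L_norm_min = min(run$objectives$L_norm),
        L_norm_max = max(run$objectives$L_norm),
        refs = run$refs
      )
      tables[[paste0("morphospace_", key)]] <- run$objectives
    }
  }

  kura <- NULL
  if (isTRUE(config$run_kuramoto)) {
    stage_msg(config, "kuramoto", "%d lambdas x %d runs x 3 modes",
              length(config$kuramoto$lambda_grid), config$kuramoto$n_runs)
    sw_b <- kuramoto_sweep(cn, "binary", config$kuramoto, partition = part_b,
                           hubs = hubs, seed = child_seed(seed, 12))
    sw_w <- kuramoto_sweep(cn, "weighted", config$kuramoto, partition = part_b,
                           hubs = hubs, seed = child_seed(seed, 13))
    sw_s <- kuramoto_sweep(cn, "weight_shuffled", config$kuramoto,
                           partition = part_b, hubs = hubs,
                           seed = child_seed(seed, 14))
    cmp <- compare_sweeps(sw_w, sw_s, stat = "dyn_mod",
                          n_perm = config$n_perm, seed = child_seed(seed, 15))
    kura <- list(modes = c("binary", "weighted", "weight_shuffled"))
    tables$kuramoto_sweep <- do.call(rbind, lapply(
      list(sw_b, sw_w, sw_s),
      function(s) cbind(mode = s$mode, s$table)))
    tables$kuramoto_weighted_vs_shuffled <- cmp
  }

  structure(list(
    metrics = metrics,
    null_summaries = null_summaries,
    partitions = partitions,
    rich_club = rich_club,
    morphospace = morpho,
    kuramoto = kura,
    tables = tables,
    config = unclass(config)[setdiff(names(config), "kuramoto")],
    kuramoto_config = unclass(config$kuramoto),
    seed = seed
  ), class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("Connectome analysis bundle\n")
  cat(sprintf("  density %.3f | C_b %.3f C_w %.3f | L_b %.3f L_w %.3f Lstep_w %.3f\n",
              x$metrics$density, x$metrics$C_b, x$metrics$C_w,
              x$metrics$L_b, x$metrics$L_w, x$metrics$Lstep_w))
  cat(sprintf("  Q %.3f (%d modules) | Q_w %.3f (%d modules) | Rand %.3f (p = %.3g)\n",
              x$partitions$binary$Q, x$partitions$binary$n_modules,
              x$partitions$weighted$Q, x$partitions$weighted$n_modules,
              x$partitions$rand$rand, x$partitions$rand$p))
  cat(sprintf("  hubs: %s\n", paste(x$rich_club$hubs, collapse = ", ")))
  invisible(x)
}

usage_text <- function() {
  paste(
    "usage: connectome-pipeline <command> [flags]",
    "commands: metrics | modularity | richclub | morphospace | kuramoto | all | synth",
    "flags: --input PATH   connectivity CSV/TSV (square weight matrix)",
    "       --weighting W  log_counts | flne | flne_log | counts",
    "       --n-null N     null ensemble size",
    "       --n-perm N     permutations per test",
    "       --seed S       integer seed",
    "       --out DIR      output directory (required)",
    "       --fast         scaled-down smoke settings",
    "       --config PATH  YAML file overriding any of the above",
    sep = "\n")
}

parse_cli_flags <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--fast") { flags$fast <- TRUE; i <- i + 1; next }
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    key <- gsub("-", "_", key)
    if (!key %in% c("input", "weighting", "n_null", "n_perm", "seed", "out", "config"))
      stopf("unknown flag '%s'", a)
    if (i == length(argv)) stopf("flag '%s' needs a value", a)
    flags[[key]] <- argv[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`metrics`, `modularity`, `richclub`,
#' `morphospace`, `kuramoto`, `all`, `synth`) from an argument vector; the
#' installed script `inst/scripts/connectome-pipeline.R` forwards
#' `commandArgs(TRUE)` here. `synth` generates a synthetic study-condition
#' connectome and writes it as a CSV; every other command analyses `--input`
#' and writes a result bundle to `--out`.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli <- function(argv) {
  status <- tryCatch({
    if (length(argv) < 1) stopf("missing command\n%s", usage_text())
    cmd <- argv[1]
    cmds <- c("metrics", "modularity", "richclub", "morphospace", "kuramoto",
              "all", "synth")
    if (!cmd %in% cmds) stopf("unknown command '%s'\n%s", cmd, usage_text())
    flags <- parse_cli_flags(argv[-1])
    if (!is.null(flags$config)) {
      yml <- yaml::read_yaml(flags$config)
      for (k in names(yml)) if (is.null(flags[[k]])) flags[[k]] <- yml[[k]]
    }
    if (is.null(flags$out)) stopf("--out is required\n%s", usage_text())
    seed <- as.integer(flags$seed %||% 1L)

    if (cmd == "synth") {
      cn <- generate_connectome(synth_spec(), seed = seed)
      dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(flags$out, "net.csv")
      utils::write.csv(data.frame(region = cn$labels, cn$W,
                                  check.names = FALSE),
                       path, row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(region = cn$labels, k_in_ext = cn$k_in_ext),
                       file.path(flags$out, "k_in_ext.csv"),
                       row.names = FALSE, quote = FALSE)
      message("wrote ", path)
      return(invisible(0L))
    }

    if (is.null(flags$input)) stopf("--input is required for '%s'", cmd)
    if (!file.exists(flags$input)) stopf("input file not found: %s", flags$input)
    cfg <- pipeline_config(
      weighting = flags$weighting %||% "log_counts",
      n_null = as.integer(flags$n_null %||% 1000L),
      n_perm = as.integer(flags$n_perm %||% 1000L),
      run_morphospace = cmd %in% c("morphospace"),
      run_kuramoto = cmd %in% c("kuramoto"),
      seed = seed,
      fast = isTRUE(flags$fast)
    )
    bundle <- run_all(flags$input, cfg)
    write_report(bundle, flags$out)
    message("wrote bundle to ", flags$out)
    invisible(0L)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(1L)
  })
  invisible(status %||% 0L)
}
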