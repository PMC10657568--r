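#' Run the integrative delimitation pipeline from a configuration
#'
#' Drives the full analysis: for each landmark aspect, generalized
#' Procrustes analysis (with sliding semilandmarks when a sliders file
#' is given), the tangent-space check, Procrustes ANOVA, relative warps,
#' between-group PCA with deformation grids along the leading axis, CVA
#' with a jackknifed confusion matrix, and pairwise PERMANOVA; for the
#' barcode alignment, the p-distance matrix, threshold partitions and
#' the single-linkage merge profile with a Newick dendrogram.  All
#' tables are written as CSV under `out_dir` and every headline
#' statistic is collected into a JSON summary (`summary.json`), so two
#' runs with the same configuration and seed produce byte-identical
#' summaries.  A plain-text run log records versions, parameters and
#' stage wall-times.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 1
#' out_dir: results
#' thresholds: [0.02, 0.03, 0.04, 0.05]
#' n_perm_anova: 999
#' n_perm_permanova: 999
#' retain: 0.99
#' slide_mode: bending_energy
#' replicate_policy: all        # or: average (per specimen/colony)
#' nest_site_in_species: true
#' group_column: species
#' anova_factors: [species, site, replicate_id]
#' shapes:
#'   head: {tps: head.tps, sliders: head_sliders.txt, labels: labels.csv}
#' barcode: {fasta: coi.fasta}
#' }
#' Alternatively a `simulate:` block with `shapes:` ([shape_sim_spec()]
#' arguments) and/or `sequences:` ([seq_sim_spec()] arguments) generates
#' synthetic inputs in place of files.
#'
#' @param config path to a YAML configuration file, or a list.
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- pipeline_defaults(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...),
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("morphodelim %s | R %s | seed %d",
       as.character(utils::packageVersion("morphodelim")),
       paste(R.version$major, R.version$minor, sep = "."), cfg$seed)
  logf("parameters: slide_mode=%s retain=%s replicate_policy=%s nesting=%s",
       cfg$slide_mode, format(cfg$retain), cfg$replicate_policy,
       cfg$nest_site_in_species)

  summary <- list(seed = cfg$seed,
                  parameters = cfg[c("thresholds", "n_perm_anova",
                                     "n_perm_permanova", "retain",
                                     "slide_mode", "replicate_policy",
                                     "nest_site_in_species")],
                  shapes = list(), barcode = NULL)

  shape_inputs <- gather_shape_inputs(cfg)
  for (aspect in names(shape_inputs)) {
    t0 <- Sys.time()
    summary$shapes[[aspect]] <-
      run_shape_stage(shape_inputs[[aspect]], aspect, cfg)
    logf("aspect '%s' done in %.1fs", aspect,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  seqs <- gather_barcode_input(cfg)
  if (!is.null(seqs)) {
    t0 <- Sys.time()
    summary$barcode <- run_barcode_stage(seqs, cfg)
    logf("barcode stage done in %.1fs",
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("summary written")
  invisible(summary)
}

pipeline_defaults <- function(config) {
  defaults <- list(seed = 1L, out_dir = "morphodelim_results",
                   thresholds = c(0.02, 0.03, 0.04, 0.05),
                   n_perm_anova = 999L, n_perm_permanova = 999L,
                   retain = 0.99, slide_mode = "bending_energy",
                   replicate_policy = "all", nest_site_in_species = TRUE,
                   group_column = "species",
                   anova_factors = c("species", "site", "replicate_id"),
                   shapes = NULL, barcode = NULL, simulate = NULL)
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg$thresholds <- as.numeric(unlist(cfg$thresholds))
  if (any(cfg$thresholds < 0 | cfg$thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  cfg
}

gather_shape_inputs <- function(cfg) {
  out <- list()
  if (!is.null(cfg$simulate$shapes)) {
    args <- cfg$simulate$shapes
    if (is.null(args$seed)) args$seed <- cfg$seed
    ds <- simulate_shapes(do.call(shape_sim_spec, args))
    out[["synthetic"]] <- list(dataset = ds, sliders = attr(ds, "sliders"))
  }
  for (aspect in names(cfg$shapes)) {
    sp <- cfg$shapes[[aspect]]
    if (is.null(sp$tps)) stop("aspect '", aspect, "': no 'tps' path")
    ds <- stage("read_tps", aspect, read_tps(sp$tps,
      apply_scale = sp$apply_scale %||% TRUE,
      invert_y = sp$invert_y %||% FALSE))
    if (!is.null(sp$labels))
      ds <- stage("labels", aspect,
                  attach_labels(ds, sp$labels,
                                colony_regex = sp$colony_regex))
    sliders <- NULL
    if (!is.null(sp$sliders))
      sliders <- stage("read_sliders", aspect, read_sliders(sp$sliders, ds$k))
    out[[aspect]] <- list(dataset = ds, sliders = sliders)
  }
  out
}

gather_barcode_input <- function(cfg) {
  if (!is.null(cfg$simulate$sequences)) {
    args <- cfg$simulate$sequences
    if (is.null(args$seed)) args$seed <- cfg$seed
    if (!is.null(args$between) && !is.matrix(args$between) &&
        length(args$between) > 1L)
      args$between <- matrix(unlist(args$between),
                             nrow = length(args$between), byrow = TRUE)
    return(simulate_sequences(do.call(seq_sim_spec, args)))
  }
  if (is.null(cfg$barcode$fasta)) return(NULL)
  stage("read_fasta", "barcode", read_fasta(cfg$barcode$fasta))
}

stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed for '", input, "': ",
         conditionMessage(e), call. = FALSE))
}

average_replicates <- function(ds) {
  if (is.null(ds$labels$colony)) return(ds)
  key <- ds$labels$colony
  if (!is.null(ds$labels$specimen)) key <- ds$labels$specimen
  groups <- split(seq_len(ds$n), key)
  coords <- array(0, dim = c(ds$k, 2L, length(groups)))
  for (i in seq_along(groups))
    coords[, , i] <- apply(ds$coords[, , groups[[i]], drop = FALSE],
                           c(1L, 2L), mean)
  first <- vapply(groups, `[`, integer(1), 1L)
  lab <- ds$labels[first, setdiff(names(ds$labels), "replicate_id"),
                   drop = FALSE]
  lab$id <- names(groups)
  shape_dataset(coords, ids = names(groups), labels = lab)
}

run_shape_stage <- function(input, aspect, cfg) {
  ds <- input$dataset
  if (cfg$replicate_policy == "average") ds <- average_replicates(ds)
  aligned <- stage("gpa", aspect,
                   gpa(ds, sliders = input$sliders,
                       slide_mode = cfg$slide_mode))
  tc <- stage("tangent_check", aspect, tangent_check(aligned))
  factors <- intersect(cfg$anova_factors, names(ds$labels))
  factors <- factors[vapply(factors, function(f)
    length(unique(ds$labels[[f]])) > 1L, logical(1))]
  anova <- if (length(factors))
    stage("procrustes_anova", aspect,
          procrustes_anova(aligned, factors, n_perm = cfg$n_perm_anova,
                           seed = cfg$seed,
                           nest_site_in_species = cfg$nest_site_in_species))
  warps <- stage("relative_warps", aspect, relative_warps(aligned))
  grp <- cfg$group_column
  have_groups <- !is.null(ds$labels[[grp]]) &&
    length(unique(ds$labels[[grp]])) > 1L
  pca <- cv <- jk <- pw <- NULL
  if (have_groups) {
    pca <- stage("between_group_pca", aspect,
                 between_group_pca(aligned, grp))
    rng <- range(pca$scores[, 1L])
    for (m in rng) {
      ad <- axis_deformation(aligned$consensus,
                             matrix(pca$axes[, 1L], ncol = 2L), m)
      write.csv(ad$grid$jacobian,
                file.path(cfg$out_dir,
                          sprintf("%s_grid_PC1_%+.3f.csv", aspect, m)),
                row.names = FALSE)
    }
    cv <- stage("cva", aspect, cva(warps, grp, retain = cfg$retain))
    jk <- stage("jackknife_classify", aspect,
                jackknife_classify(warps, grp, retain = cfg$retain))
    pw <- stage("pairwise_permanova", aspect,
                pairwise_permanova(warps, grp,
                                   n_perm = cfg$n_perm_permanova,
                                   seed = cfg$seed))
  }
  write_shape_outputs(aspect, cfg$out_dir, aligned, anova, warps, cv, jk, pw)
  list(n = ds$n, k = ds$k,
       gpa = list(iterations = aligned$n_iterations,
                  converged = aligned$converged),
       tangent = list(slope = tc$slope, correlation = tc$correlation),
       anova = if (!is.null(anova))
         list(factors = rownames(anova),
              percent_ss = as.numeric(anova$Rsq_pct),
              F = as.numeric(anova$F), p = as.numeric(anova$p)),
       pca = if (!is.null(pca))
         list(percent_group_mean = as.numeric(pca$percent_variance),
              percent_total_top5 =
                sum(utils::head(pca$percent_total_variance, 5L))),
       cva = if (!is.null(cv))
         list(percent = as.numeric(cv$percent_variance),
              cv1_plus_cv2 = sum(utils::head(cv$percent_variance, 2L)),
              retained = cv$retained),
       jackknife = if (!is.null(jk)) list(accuracy = jk$accuracy),
       permanova = if (!is.null(pw)) list(tests = pw$tests))
}

write_shape_outputs <- function(aspect, out_dir, aligned, anova, warps,
                                cv, jk, pw) {
  pre <- function(nm) file.path(out_dir, paste0(aspect, "_", nm))
  Y <- as_score_matrix(aligned)
  write.csv(data.frame(id = aligned$ids,
                       centroid_size = as.numeric(aligned$centroid_sizes), Y),
            pre("aligned.csv"), row.names = FALSE)
  cons <- shape_dataset(array(aligned$consensus,
                              dim = c(aligned$k, 2L, 1L)),
                        ids = paste0(aspect, "_consensus"))
  write_tps(cons, pre("consensus.tps"))
  if (!is.null(anova))
    write.csv(cbind(term = rownames(anova), as.data.frame(anova)),
              pre("anova.csv"), row.names = FALSE)
  write.csv(data.frame(id = warps$ids %||% seq_len(nrow(warps$scores)),
                       warps$scores),
            pre("warp_scores.csv"), row.names = FALSE)
  if (!is.null(cv))
    write.csv(data.frame(id = rownames(cv$scores) %||%
                           seq_len(nrow(cv$scores)), cv$scores),
              pre("cva_scores.csv"), row.names = FALSE)
  if (!is.null(jk))
    write.csv(as.data.frame.matrix(jk$table), pre("confusion.csv"))
  if (!is.null(pw))
    write.csv(pw$tests, pre("pairwise_permanova.csv"), row.names = FALSE)
}

run_barcode_stage <- function(seqs, cfg) {
  dm <- stage("p_distance_matrix", "barcode", p_distance_matrix(seqs))
  write.csv(dm$distance, file.path(cfg$out_dir, "p_distances.csv"))
  write_phylip(dm, file.path(cfg$out_dir, "p_distances.phy"))
  partitions <- list()
  for (t in cfg$thresholds) {
    part <- stage("objective_cluster", "barcode", objective_cluster(dm, t))
    write.csv(data.frame(id = names(part$assignment),
                         cluster = as.integer(part$assignment)),
              file.path(cfg$out_dir,
                        sprintf("partition_t%.3f.csv", t)),
              row.names = FALSE)
    partitions[[sprintf("%.3f", t)]] <-
      list(threshold = t, n_clusters = part$n_clusters)
  }
  prof <- stage("merge_profile", "barcode", merge_profile(dm))
  profile_newick(prof, file.path(cfg$out_dir, "merge_profile.nwk"))
  list(n_sequences = length(seqs$ids), length_bp = seqs$length,
       partitions = partitions,
       merge_heights_pct =
         round(100 * sort(prof$merges$height, decreasing = TRUE), 1))
}

# Square PHYLIP distance matrix.
write_phylip <- function(dm, path) {
  n <- length(dm$ids)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste0(formatC(substr(dm$ids[i], 1L, 10L), width = -11),
                      paste(sprintf("%.6f", dm$distance[i, ]),
                            collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
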