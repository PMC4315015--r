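# End-to-end orchestration: simulate (or load) -> preprocess -> group ICA at
# two model orders -> dual regression -> spatio-temporal labeling -> temporal
# (amplitude, netmat) and spatial (cluster-permutation) group statistics,
# with every number reproducible from one master seed.

#' Build a validated pipeline configuration
#'
#' @param input_dir directory of per-subject NIfTI + `subjects.tsv` to analyze
#'   instead of a synthetic scene (NULL = simulate the default scene).
#' @param n_per_group,n_volumes,tr_s,noise_sd,amplitude_ratio,coupling_delta
#'   synthetic-scene parameters (see [default_scene()]).
#' @param fwhm_mm,highpass_cutoff_hz preprocessing parameters.
#' @param low_D,high_D group-ICA model orders (low_D < high_D).
#' @param z_thresh map binarization threshold for Dice matching.
#' @param theta_dc,theta_tc labeling thresholds.
#' @param noise_rule `"or"` or `"and"` (see [assign_labels()]).
#' @param n_perm permutations for all permutation tests.
#' @param alpha significance level for reported flags.
#' @param cluster_forming_p voxelwise one-sided p forming clusters.
#' @param direction tested contrast for spatial maps (`"A>B"` or `"B>A"`).
#' @param connectivity cluster connectivity.
#' @param n_restarts ICA restarts.
#' @param des_norm dual-regression stage-2 design normalization.
#' @param variance_normalize variance-normalize voxel series before
#'   concatenation.
#' @param focus_parents low-D component ids to analyze (NULL = every
#'   reference network that received at least one member).
#' @param figures write PNG figures.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, n_per_group = 20,
                            n_volumes = 160, tr_s = 2.5, noise_sd = 1,
                            amplitude_ratio = 0.7, coupling_delta = 0.2,
                            fwhm_mm = 5, highpass_cutoff_hz = 0.01,
                            low_D = 3, high_D = 7, z_thresh = 3,
                            theta_dc = 0.1, theta_tc = 0.4,
                            noise_rule = "or", n_perm = 1000, alpha = 0.05,
                            cluster_forming_p = 0.05, direction = "A>B",
                            connectivity = 26, n_restarts = 3,
                            des_norm = TRUE, variance_normalize = FALSE,
                            focus_parents = NULL, figures = TRUE, seed = 1) {
  if (!(low_D < high_D)) stop("low_D must be < high_D")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Per-parent member components, excluding noise and unknown
#'
#' @param labels a `label_assignment`.
#' @param parents reference-network (low-D component) ids to select.
#' @return named list: for each parent, the integer ids of its labeled high-D
#'   member components. Noise and unknown components never appear.
#' @export
select_focus <- function(labels, parents) {
  stopifnot(inherits(labels, "label_assignment"))
  lab <- labels$labels
  present <- unique(lab$label[!(lab$label %in% c("noise", "unknown"))])
  missing <- setdiff(as.character(parents), present)
  if (length(missing))
    stop("parent id(s) absent from the label set: ",
         paste(missing, collapse = ", "))
  out <- lapply(as.character(parents),
                function(p) lab$component[lab$label == p])
  names(out) <- as.character(parents)
  if (sum(lengths(out)) == 0L) stop("empty selection")
  out
}

stage_log <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[%s] starting", stage))
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1f s", stage,
                  proc.time()[["elapsed"]] - t0))
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage from one configuration and writes label tables,
#' amplitude and netmat comparison tables, cluster tables, figures, and a
#' machine-readable manifest under `out_dir`. Re-running with the same
#' configuration reproduces all statistics tables byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the report bundle (all intermediate objects and table paths),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  data <- stage_log("simulate/load", {
    if (is.null(config$input_dir)) {
      sc <- default_scene(n_per_group = config$n_per_group,
                          n_volumes = config$n_volumes, tr_s = config$tr_s,
                          noise_sd = config$noise_sd,
                          amplitude_ratio = config$amplitude_ratio,
                          coupling_delta = config$coupling_delta,
                          seed = derive_seed(config$seed, "scene"))
      list(subjects = sc$dataset$subjects,
           group_labels = sc$dataset$group_labels, scene = sc)
    } else {
      c(read_dataset(config$input_dir, tr_s = config$tr_s),
        list(scene = NULL))
    }
  })

  pre <- stage_log("preprocess", {
    pp <- preproc_params(config$fwhm_mm, config$highpass_cutoff_hz,
                         data$subjects[[1]]$tr_s)
    lapply(data$subjects, preprocess_subject, params = pp)
  })

  concat <- stage_log("concatenate", concatenate_subjects(
    pre, variance_normalize = config$variance_normalize))

  ica_low <- stage_log(sprintf("group-ica D=%d", config$low_D),
    run_group_ica(concat, config$low_D,
                  seed = derive_seed(config$seed, "ica-low"),
                  n_restarts = config$n_restarts))
  ica_high <- stage_log(sprintf("group-ica D=%d", config$high_D),
    run_group_ica(concat, config$high_D,
                  seed = derive_seed(config$seed, "ica-high"),
                  n_restarts = config$n_restarts))

  dr_low <- stage_log("dual-regression low",
    dual_regression(pre, ica_low, des_norm = config$des_norm))
  dr_high <- stage_log("dual-regression high",
    dual_regression(pre, ica_high, des_norm = config$des_norm))

  labeling <- stage_log("labeling", {
    dc <- dice_matrix(ica_high, ica_low, z_thresh = config$z_thresh)
    tc <- temporal_corr_matrix(dr_high$timeseries, dr_low$timeseries)
    assign_labels(match_evidence(dc, tc, config$theta_dc, config$theta_tc,
                                 config$z_thresh),
                  noise_rule = config$noise_rule)
  })

  parents <- config$focus_parents
  if (is.null(parents)) {
    lab <- labeling$labels$label
    parents <- sort(as.integer(unique(lab[!(lab %in%
                                              c("noise", "unknown"))])))
  }
  focus <- stage_log("select-focus", select_focus(labeling, parents))
  members <- unlist(focus, use.names = FALSE)
  parent_of_member <- rep(as.integer(names(focus)), lengths(focus))
  groups <- vapply(data$subjects, `[[`, "", "group")

  amp_mat <- function(ts_list, cols) {
    out <- matrix(0, length(ts_list), length(cols),
                  dimnames = list(names(ts_list), NULL))
    for (s in seq_along(ts_list))
      out[s, ] <- amplitude(ts_list[[s]][, cols, drop = FALSE])
    out
  }
  temporal <- stage_log("temporal-stats", {
    amp_low <- amp_mat(dr_low$timeseries, parents)
    colnames(amp_low) <- sprintf("lowD_%d", parents)
    amp_high <- amp_mat(dr_high$timeseries, members)
    colnames(amp_high) <- sprintf("highD_%d", members)
    cmp_low <- compare_groups(amp_low, groups,
                              family = rep("lowD", ncol(amp_low)),
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed, "amp-low"))
    cmp_high <- compare_groups(amp_high, groups,
                               family = sprintf("parent_%d",
                                                parent_of_member),
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, "amp-high"))
    edges <- edge_table(parent_of_member)
    nm <- lapply(dr_high$timeseries, function(m)
      netmat(m[, members, drop = FALSE]))
    z <- matrix(0, length(nm), nrow(edges),
                dimnames = list(names(nm),
                                sprintf("edge_%d~%d", members[edges$i],
                                        members[edges$j])))
    for (s in seq_along(nm))
      z[s, ] <- nm[[s]][cbind(edges$i, edges$j)]
    cmp_net <- compare_groups(z, groups, family = edges$family,
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed, "netmat"))
    list(amplitude_low = amp_low, amplitude_high = amp_high,
         cmp_amplitude_low = cmp_low, cmp_amplitude_high = cmp_high,
         edges = edges, netmats = nm, netmat_z = z, cmp_netmat = cmp_net)
  })

  spatial <- stage_log("spatial-stats", {
    is_a <- groups == "A"
    run_one <- function(dr, comp, tag) {
      stack_group <- function(keep) {
        arrs <- lapply(dr$maps[keep], function(ms)
          array(maps_to_array(ms)[, , , comp], ms$dim))
        array(unlist(arrs), c(dim(arrs[[1]]), length(arrs)))
      }
      cluster_permutation_test(stack_group(is_a), stack_group(!is_a),
                               cluster_forming_p = config$cluster_forming_p,
                               n_perm = config$n_perm,
                               direction = config$direction,
                               connectivity = config$connectivity,
                               mask = ica_low$mask,
                               seed = derive_seed(config$seed,
                                                  paste0("cluster-", tag)))
    }
    res_low <- lapply(parents, function(j)
      run_one(dr_low, j, sprintf("low-%d", j)))
    names(res_low) <- sprintf("lowD_%d", parents)
    res_high <- lapply(members, function(i)
      run_one(dr_high, i, sprintf("high-%d", i)))
    names(res_high) <- sprintf("highD_%d", members)
    c(res_low, res_high)
  })

  report <- stage_log("report", {
    paths <- list()
    paths$labels <- write_tsv(labeling$labels,
                              file.path(out_dir, "labels.tsv"))
    paths$dc <- write_tsv(as.data.frame(labeling$evidence$DC),
                          file.path(out_dir, "dice_matrix.tsv"))
    paths$tc <- write_tsv(as.data.frame(labeling$evidence$TC),
                          file.path(out_dir, "temporal_corr_matrix.tsv"))
    amp_tab <- rbind(
      data.frame(dimension = "low", temporal$cmp_amplitude_low),
      data.frame(dimension = "high", temporal$cmp_amplitude_high))
    amp_tab$significant <- amp_tab$p_fwe < config$alpha
    paths$amplitude_tests <- write_tsv(amp_tab,
                                       file.path(out_dir,
                                                 "amplitude_tests.tsv"))
    paths$amplitude_low <- write_tsv(
      data.frame(subject = rownames(temporal$amplitude_low),
                 group = groups, temporal$amplitude_low),
      file.path(out_dir, "amplitude_lowD.tsv"))
    paths$amplitude_high <- write_tsv(
      data.frame(subject = rownames(temporal$amplitude_high),
                 group = groups, temporal$amplitude_high),
      file.path(out_dir, "amplitude_highD.tsv"))
    net_tab <- temporal$cmp_netmat
    net_tab$significant <- net_tab$p_fwe < config$alpha
    paths$netmat_tests <- write_tsv(net_tab,
                                    file.path(out_dir, "netmat_tests.tsv"))
    cl_rows <- do.call(rbind, lapply(names(spatial), function(nm) {
      cl <- spatial[[nm]]$clusters
      if (!nrow(cl)) return(NULL)
      data.frame(component = nm, cl)
    }))
    if (is.null(cl_rows))
      cl_rows <- data.frame(component = character(0), cluster = integer(0),
                            size = integer(0), p_fwe = numeric(0))
    paths$clusters <- write_tsv(cl_rows, file.path(out_dir, "clusters.tsv"))
    manifest <- list(
      package = "subnetica",
      version = as.character(utils::packageVersion("subnetica")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = unclass(config)[!vapply(unclass(config), is.null,
                                       TRUE)],
      stage_seeds = list(
        scene = derive_seed(config$seed, "scene"),
        ica_low = derive_seed(config$seed, "ica-low"),
        ica_high = derive_seed(config$seed, "ica-high")),
      n_subjects = length(data$subjects),
      labels = table(labeling$labels$label))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    paths$manifest <- file.path(out_dir, "manifest.json")
    if (isTRUE(config$figures))
      paths$figures <- tryCatch(
        write_figures(out_dir, ica_low, ica_high, temporal, groups,
                      parent_of_member),
        error = function(e) {
          warning("figure generation failed: ", conditionMessage(e))
          NULL
        })
    paths
  })

  invisible(list(config = config, scene = data$scene, labeling = labeling,
                 ica_low = ica_low, ica_high = ica_high, dr_low = dr_low,
                 dr_high = dr_high, focus = focus, temporal = temporal,
                 spatial = spatial, paths = report, out_dir = out_dir))
}

# Figure-2-style netmat heatmaps and a component-map montage.
write_figures <- function(out_dir, ica_low, ica_high, temporal, groups,
                          parent_of_member) {
  paths <- character(0)
  z <- temporal$netmat_z
  edges <- temporal$edges
  k <- max(edges$j)
  mean_mat <- function(rows) {
    m <- matrix(0, k, k)
    mu <- colMeans(z[rows, , drop = FALSE])
    m[cbind(edges$i, edges$j)] <- mu
    m[cbind(edges$j, edges$i)] <- mu
    m
  }
  mats <- list(group_A = mean_mat(groups == "A"),
               group_B = mean_mat(groups == "B"))
  mats$difference <- mats$group_A - mats$group_B
  f <- file.path(out_dir, "netmat_heatmaps.png")
  grDevices::png(f, width = 1200, height = 420)
  graphics::par(mfrow = c(1, 3), mar = c(2, 2, 3, 1))
  for (nm in names(mats)) {
    graphics::image(seq_len(k), seq_len(k), t(mats[[nm]][k:1, ]),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    main = paste("mean Fisher z:", nm), xlab = "", ylab = "",
                    axes = FALSE)
    graphics::box()
  }
  grDevices::dev.off()
  paths <- c(paths, f)
  for (res in list(ica_low, ica_high)) {
    arr <- maps_to_array(res)
    f <- file.path(out_dir, sprintf("ica_maps_D%d.png", res$D))
    grDevices::png(f, width = 220 * res$D, height = 240)
    graphics::par(mfrow = c(1, res$D), mar = c(1, 1, 2, 1))
    mid <- round(dim(arr)[3] / 2)
    for (d in seq_len(res$D)) {
      graphics::image(arr[, , mid, d],
                      col = grDevices::hcl.colors(64, "YlOrRd",
                                                  rev = TRUE),
                      main = sprintf("D=%d IC%d (z=%d)", res$D, d, mid),
                      axes = FALSE)
    }
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  paths
}
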