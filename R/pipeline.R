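#' Default pipeline configuration
#'
#' Every stage parameter with its default; user configs (YAML) are merged
#' over this recursively, so a config file only states what it changes.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "dynacomm_out",
    systems = list(),
    selection = list(exclude_chains = list(),
                     ligand_atoms = list(GTP = "PB", GDP = "PB"),
                     include_ligands = TRUE, rep_atom = "CA"),
    align = list(enabled = TRUE, reference = "mean"),
    cluster = list(cutoff_nm = 0.15, linkage = "average", stride = 1L,
                   max_frames = 1500L),
    contacts = list(cutoff_nm = 0.45, group_a_chains = NULL,
                    group_b_chains = NULL, reference_system = NULL),
    interactions = list(enabled = TRUE, hbond_dist_nm = 0.35,
                        hbond_angle_deg = 130, saltbridge_dist_nm = 0.55,
                        hydrophobic_dist_nm = 0.40, his_protonated = FALSE,
                        stability_threshold = 0.75),
    network = list(contact_cutoff_nm = 0.45, contact_fraction = 0.75,
                   knn_k = 5L),
    mechanics = list(temperature = 300, exclude_window = 0L),
    conservation = list(msa = NULL, reference = 1L, chains = list(),
                        max_gap = 0.5)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])) && nm != "systems") {
      base[nm] <- list(merge_config(base[[nm]], override[[nm]]))
    } else {
      base[nm] <- list(override[[nm]])  # keeps explicit NULLs in place
    }
  }
  base
}

# canonical shapes so that load -> dump -> load round-trips identically
normalize_config <- function(cfg) {
  as_chr <- function(x) if (is.null(x) || length(x) == 0L) NULL else
    as.character(unlist(x))
  cfg$seed <- as.integer(cfg$seed)
  cfg$systems <- lapply(cfg$systems, function(s) {
    s$trajectories <- as.character(unlist(s$trajectories))
    if (!is.null(s$equil_frames)) s$equil_frames <- as.integer(s$equil_frames)
    s
  })
  cfg$selection$exclude_chains <- as_chr(cfg$selection$exclude_chains)
  la <- unlist(cfg$selection$ligand_atoms)
  cfg$selection$ligand_atoms <- if (is.null(la)) NULL else
    as.list(stats::setNames(as.character(la), names(la)))
  cfg$contacts["group_a_chains"] <- list(as_chr(cfg$contacts$group_a_chains))
  cfg$contacts["group_b_chains"] <- list(as_chr(cfg$contacts$group_b_chains))
  cfg$conservation["chains"] <- list(as_chr(cfg$conservation$chains))
  for (f in c("stride", "max_frames")) {
    cfg$cluster[[f]] <- as.integer(cfg$cluster[[f]])
  }
  cfg$network$knn_k <- as.integer(cfg$network$knn_k)
  cfg$mechanics$exclude_window <- as.integer(cfg$mechanics$exclude_window)
  cfg
}

#' Load (and validate) a pipeline configuration
#'
#' Reads a YAML config, merges it over [default_config()], and checks that
#' every referenced input file exists. A config round-trips:
#' `load_config(save_config(cfg))` is identical to `cfg`.
#'
#' @param path YAML file, or a list already in config shape.
#' @return a validated `PipelineConfig` list.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else {
    path
  }
  cfg <- normalize_config(merge_config(default_config(), user))
  if (length(cfg$systems) == 0L) stop("config lists no systems")
  for (s in cfg$systems) {
    for (f in c("name", "topology", "trajectories")) {
      if (is.null(s[[f]])) stop("system entry missing field: ", f)
    }
    if (!file.exists(s$topology)) {
      stop("topology not found for system ", s$name, ": ", s$topology)
    }
    for (tr in s$trajectories) {
      if (!file.exists(tr)) {
        stop("trajectory not found for system ", s$name, ": ", tr)
      }
    }
  }
  if (!is.null(cfg$conservation$msa) && !file.exists(cfg$conservation$msa)) {
    stop("MSA file not found: ", cfg$conservation$msa)
  }
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Write a configuration to YAML
#' @param config a `PipelineConfig` (or plain list).
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, per system: load, equilibrated-segment concatenation,
#' alignment, RMSD and frame clustering, contact and interaction
#' profiling, dynamical-network construction, degree and betweenness
#' centrality, and force constants; then across systems: knee-based
#' betweenness thresholding (shared threshold = the lowest per-system
#' knee), top-edge tables, contact-difference maps against the reference
#' system, interaction stability filtering, and - when an MSA is
#' configured - conservation scoring with the rigid-set summary. All
#' tables are written as CSV (networks additionally as GraphML) under
#' `output_dir`, together with a JSON manifest of inputs, parameters, seed
#' and output hashes.
#'
#' @param config a `PipelineConfig` (see [load_config()]).
#' @param stages subset of stages to run (default: all).
#' @return invisibly, the report bundle (named list of per-system and
#'   cross-system results).
#' @export
run_pipeline <- function(config,
                         stages = c("conformation", "contacts",
                                    "interactions", "network", "mechanics",
                                    "conservation")) {
  if (!inherits(config, "PipelineConfig")) config <- load_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) {
    cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ..., "\n",
        sep = "", file = file.path(out_dir, "pipeline.log"), append = TRUE)
  }
  log_line("parameters: seed=", config$seed)
  bundle <- list(systems = list())
  outputs <- character()
  geom <- interaction_geometry(
    hbond_dist_nm = config$interactions$hbond_dist_nm,
    hbond_angle_deg = config$interactions$hbond_angle_deg,
    saltbridge_dist_nm = config$interactions$saltbridge_dist_nm,
    hydrophobic_dist_nm = config$interactions$hydrophobic_dist_nm,
    his_protonated = config$interactions$his_protonated
  )
  run_stage <- function(stage, name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed for system '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  for (sysdef in config$systems) {
    name <- sysdef$name
    sdir <- file.path(out_dir, name)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    res <- list(name = name)
    log_line("system ", name, ": loading ", sysdef$topology,
             " + ", length(sysdef$trajectories), " trajectory file(s)")
    sys <- run_stage("load", name, load_system(sysdef$topology,
                                               sysdef$trajectories))
    equil <- if (is.null(sysdef$equil_frames)) 0L else sysdef$equil_frames
    sys <- run_stage("equilibration", name, concat_equilibrated(sys, equil))
    log_line("system ", name, ": ", n_frames(sys),
             " equilibrated frames (cut=", equil, " per replica)")
    nodes <- run_stage("selection", name, select_nodes(
      sys,
      exclude_chains = unlist(config$selection$exclude_chains),
      ligand_atoms = unlist(config$selection$ligand_atoms),
      rep_atom = config$selection$rep_atom,
      include_ligands = config$selection$include_ligands
    ))
    res$nodes <- nodes
    outputs <- c(outputs, write_csv(as.data.frame(nodes),
                                    file.path(sdir, "nodes.csv")))
    aligned <- if (isTRUE(config$align$enabled)) {
      run_stage("alignment", name,
                align_frames(sys, fit_atoms = nodes$atom_index,
                             reference = config$align$reference))
    } else sys
    res$system <- aligned

    if ("conformation" %in% stages) {
      rmsd <- rmsd_series(sys, atoms = nodes$atom_index)
      res$rmsd <- rmsd
      outputs <- c(outputs, write_csv(as.data.frame(rmsd),
                                      file.path(sdir, "rmsd.csv")))
      cl <- run_stage("clustering", name, cluster_frames(
        aligned, atoms = nodes$atom_index,
        cutoff = config$cluster$cutoff_nm,
        linkage = config$cluster$linkage,
        stride = config$cluster$stride,
        max_frames = config$cluster$max_frames
      ))
      res$clusters <- cl
      outputs <- c(outputs, write_csv(as.data.frame(cl),
                                      file.path(sdir, "clusters.csv")))
      res$rmsf <- rmsf_profile(aligned, nodes)
      outputs <- c(outputs, write_csv(res$rmsf,
                                      file.path(sdir, "rmsf.csv")))
      log_line("system ", name, ": ", length(attr(cl, "sizes")),
               " cluster(s) at ", config$cluster$cutoff_nm, " nm")
    }

    ga_chains <- unlist(config$contacts$group_a_chains)
    gb_chains <- unlist(config$contacts$group_b_chains)
    have_groups <- length(ga_chains) > 0L && length(gb_chains) > 0L
    if ("contacts" %in% stages && have_groups) {
      ga <- residue_group(aligned, chains = ga_chains)
      gb <- residue_group(aligned, chains = gb_chains)
      ct <- run_stage("contacts", name, contact_frequency(
        aligned, ga, gb, cutoff = config$contacts$cutoff_nm))
      res$contacts <- ct
      outputs <- c(outputs, write_csv(as.data.frame(ct),
                                      file.path(sdir, "contacts.csv")))
      outputs <- c(outputs, write_csv(attr(ct, "marginals"),
                                      file.path(sdir, "contact_marginals.csv")))
    }
    if ("interactions" %in% stages && have_groups &&
        isTRUE(config$interactions$enabled)) {
      ga <- residue_group(aligned, chains = ga_chains, heavy_only = FALSE)
      gb <- residue_group(aligned, chains = gb_chains, heavy_only = FALSE)
      ints <- run_stage("interactions", name, suppressWarnings(
        classify_interactions(aligned, ga, gb, geometry = geom)))
      res$interactions <- ints
      outputs <- c(outputs, write_csv(ints,
                                      file.path(sdir, "interactions.csv")))
    }

    if ("network" %in% stages) {
      net <- run_stage("network", name, build_network(
        aligned, nodes,
        contact_cutoff = config$network$contact_cutoff_nm,
        contact_fraction = config$network$contact_fraction,
        k = config$network$knn_k, seed = config$seed
      ))
      res$network <- net
      rep_ <- run_stage("centrality", name, betweenness_centrality(net))
      res$centrality <- rep_
      res$degree <- degree_centrality(net)
      outputs <- c(outputs,
                   write_csv(network_edges(net),
                             file.path(sdir, "edges.csv")),
                   write_csv(res$degree, file.path(sdir, "degree.csv")),
                   write_csv(rep_$node_betweenness,
                             file.path(sdir, "node_betweenness.csv")),
                   write_csv(rep_$edge_betweenness,
                             file.path(sdir, "edge_betweenness.csv")))
      write_graphml(net, file.path(sdir, "network.graphml"))
      outputs <- c(outputs, file.path(sdir, "network.graphml"))
      log_line("system ", name, ": network with ",
               sum(net$adjacency) / 2, " edges")
    }

    if ("mechanics" %in% stages) {
      fc <- run_stage("mechanics", name, force_constant_profile(
        aligned, nodes, temperature = config$mechanics$temperature,
        exclude_window = config$mechanics$exclude_window
      ))
      res$force_constants <- fc
      outputs <- c(outputs, write_csv(as.data.frame(fc),
                                      file.path(sdir, "force_constants.csv")))
    }
    bundle$systems[[name]] <- res
  }

  # ----- cross-system stages -------------------------------------------
  sys_names <- names(bundle$systems)
  if ("network" %in% stages) {
    ranked <- lapply(bundle$systems, function(r) {
      sort(r$centrality$edge_betweenness$betweenness, decreasing = TRUE)
    })
    kn <- knee_threshold(ranked)
    bundle$knees <- kn$knees
    bundle$threshold <- kn$threshold
    for (name in sys_names) {
      r <- bundle$systems[[name]]
      te <- top_edges(r$network, r$centrality, kn$threshold)
      bundle$systems[[name]]$top_edges <- te
      outputs <- c(outputs, write_csv(
        te$edges, file.path(out_dir, name, "top_edges.csv")))
    }
    jsonlite::write_json(list(knees = as.list(kn$knees),
                              threshold = kn$threshold),
                         file.path(out_dir, "knee_threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(out_dir, "knee_threshold.json"))
  }
  ref_name <- config$contacts$reference_system
  if ("contacts" %in% stages && !is.null(ref_name) &&
      length(sys_names) > 1L) {
    ref_ct <- bundle$systems[[ref_name]]$contacts
    for (name in setdiff(sys_names, ref_name)) {
      cd <- contact_difference(bundle$systems[[name]]$contacts, ref_ct)
      bundle$systems[[name]]$contact_difference <- cd
      outputs <- c(outputs, write_csv(
        cd, file.path(out_dir, name, "contact_difference.csv")))
    }
  }
  if ("interactions" %in% stages &&
      !is.null(bundle$systems[[1L]]$interactions)) {
    stab <- stable_interactions(
      lapply(bundle$systems, `[[`, "interactions"),
      threshold = config$interactions$stability_threshold
    )
    bundle$stable_interactions <- stab
    outputs <- c(outputs, write_csv(
      stab, file.path(out_dir, "stable_interactions.csv")))
  }
  if ("conservation" %in% stages && !is.null(config$conservation$msa)) {
    msa <- read_msa(config$conservation$msa,
                    reference = config$conservation$reference)
    prof <- stereochemical_entropy_profile(msa,
                                           max_gap = config$conservation$max_gap)
    bundle$conservation <- prof
    outputs <- c(outputs, write_csv(as.data.frame(prof),
                                    file.path(out_dir, "conservation.csv")))
    chains <- unlist(config$conservation$chains)
    if (length(chains) > 0L && "mechanics" %in% stages) {
      first <- bundle$systems[[1L]]
      mapping <- map_conservation(prof, first$system, chains)
      fc <- first$force_constants
      key <- res_key(mapping$chain, mapping$resid)
      ne <- mapping$ne[match(res_key(fc$chain, fc$resid), key)]
      sel <- !is.na(ne) & ne >= 0
      rs <- rigid_set_conservation(fc[sel, , drop = FALSE], ne[sel])
      bundle$rigid_set <- rs
      outputs <- c(outputs, write_csv(
        rs, file.path(out_dir, "rigid_set_conservation.csv")))
    }
  }

  manifest <- list(
    inputs = lapply(config$systems, function(s) {
      list(name = s$name, topology = s$topology,
           trajectories = as.list(s$trajectories),
           equil_frames = s$equil_frames)
    }),
    parameters = unclass(config)[setdiff(names(config),
                                         c("systems", "output_dir"))],
    seed = config$seed,
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("done: ", length(outputs), " output files")
  invisible(bundle)
}
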