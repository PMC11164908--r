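## End-to-end orchestration on synthetic data: generate -> curate ->
## build/split HMMs -> search + confirm -> dedup/cluster -> profile
## network + MCL -> pocket classification -> cofactor prediction ->
## representative selection, with a run manifest whose counts balance.

PIPELINE_DEFAULTS <- list(
  seed = 1L,
  ## synthetic study conditions
  n_groups = 3L, n_members = 20L, n_decoys = 40L, n_obsolete = 2L,
  mutation_rate = 0.05,
  length_range = c(250L, 500L),
  ## screen
  score_threshold = 50,
  ## clustering
  cluster_identity = 0.8, cluster_coverage = 0.8,
  dedup_identity = 1.0,
  min_family_size = 2L,
  ## profile network
  min_probability = 0.95, network_coverage = 0.75, inflation = 2,
  ## pocket classification
  min_cluster_size = 15L, cut_height = 0.5,
  modeling_min_identity = 0.23,
  noise_sd = 0.5, match_cutoff = 3,
  ## selection
  tree_redundancy_identity = 0.95, tree_redundancy_coverage = 0.9,
  n_representatives = 6L, per_group_minimum = 1L,
  ## stage toggles
  run_network = TRUE, run_pockets = TRUE, run_cofactor = TRUE,
  run_selection = TRUE
)

#' Build and validate a pipeline configuration
#'
#' Defaults reproduce the workflow's published operating points: 50-bit
#' screen threshold, 0.8/0.8 family clustering, exact-duplicate
#' redundancy removal, 0.95 probability and 0.75 coverage network
#' admission with inflation 2, 23% modeling identity gate, 15-member
#' pocket-cluster retention and 250-500 residue length bounds. Unknown
#' keys are rejected; thresholds are range-checked.
#'
#' @param ... Overrides of the defaults (or a YAML file via `file`).
#' @param file Optional YAML config file read before applying `...`.
#' @return A validated named list of class `pocketfamConfig`.
#' @export
#' @examples
#' cfg <- pipelineConfig(n_members = 5, n_decoys = 10)
#' cfg$score_threshold
pipelineConfig <- function(..., file = NULL) {
  cfg <- PIPELINE_DEFAULTS
  apply_over <- function(cfg, over) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
  cfg <- apply_over(cfg, list(...))
  frac <- c("cluster_identity", "cluster_coverage", "dedup_identity",
            "min_probability", "network_coverage",
            "modeling_min_identity", "tree_redundancy_identity",
            "tree_redundancy_coverage")
  for (k in frac)
    if (cfg[[k]] <= 0 || cfg[[k]] > 1)
      stop("config '", k, "' must be in (0, 1]")
  if (cfg$inflation <= 1) stop("inflation must exceed 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$length_range[1] > cfg$length_range[2])
    stop("length_range must be increasing")
  structure(cfg, class = "pocketfamConfig")
}

#' Run the full synthetic-demo pipeline
#'
#' Generates a synthetic superfamily of `n_groups` active-site groups
#' sharing one sequence backbone but carrying distinct planted pocket
#' motifs and cofactor windows (the last group lacks the catalytic P3
#' glutamate), plus background decoys. It then curates the seed group,
#' builds and anchor-splits its profile HMM, screens the database with
#' both domain profiles, confirms two-domain hits, removes redundancy,
#' clusters families, builds and Markov-clusters the profile network,
#' extracts and classifies pocket fingerprints from noisy toy
#' structures, predicts cofactor specificity, and selects diverse
#' representatives on a neighbor-joining tree. A manifest records the
#' config, seeds, per-stage counts and warnings.
#'
#' @param config A [pipelineConfig()].
#' @param outdir Optional directory for artifacts (FASTA, TSV, Newick,
#'   manifest YAML).
#' @return A list of stage artifacts plus `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
  stopifnot(inherits(config, "pocketfamConfig"))
  warnings_log <- character()
  noteWarn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  counts <- list()
  seed <- as.integer(config$seed)

  ## --- generate ------------------------------------------------------
  base <- familySpec("G1", config$n_members,
                     length_range = config$length_range,
                     mutation_rate = config$mutation_rate,
                     cofactor_class = "NAD", seed = seed)
  specs <- list(base)
  classes <- c("NAD", "NADP", "dual")
  if (config$n_groups > 1L) for (g in 2L:config$n_groups) {
    specs[[g]] <- variantSpec(base, paste0("G", g), seed = seed + g,
                              cofactor_class = classes[((g - 1L) %%
                                                          3L) + 1L],
                              catalytic = g < config$n_groups)
  }
  fams <- lapply(specs, generateFamily)
  members <- do.call(rbind, lapply(fams, `[[`, "records"))
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
  decoys <- generateDecoys(config$n_decoys,
                           length_range = config$length_range,
                           seed = seed + 101L)
  db <- rbind(members, decoys$records)
  truth <- rbind(truth, decoys$truth)
  counts$database <- nrow(db)

  ## --- curate the seed group ----------------------------------------
  seedset <- fams[[1L]]$records
  if (config$n_obsolete > 0L)
    seedset$obsolete[seq_len(min(config$n_obsolete, nrow(seedset)))] <- TRUE
  cur <- withCallingHandlers(
    curateSeedSet(seedset, config$length_range[1], config$length_range[2]),
    warning = noteWarn)
  counts$seed_input <- unname(cur$report[["n_input"]])
  counts$seed_retained <- unname(cur$report[["n_retained"]])
  counts$seed_removed <- counts$seed_input - counts$seed_retained

  ## --- build + split the seed profile -------------------------------
  seed_aln <- data.frame(id = cur$retained$id,
                         aligned = cur$retained$residues,
                         stringsAsFactors = FALSE)
  anchor <- unname(specs[[1L]]$blocks[["rossmann"]])
  dsplit <- splitProfile(seed_aln, seed_aln$id[1L], anchor,
                        name = "seed_family")

  ## --- screen + confirm ---------------------------------------------
  hits_c <- searchProfile(dsplit@cProfile, db, config$score_threshold)
  hits_n <- searchProfile(dsplit@nProfile, db, config$score_threshold)
  confirmed_ids <- confirmTwoDomain(hits_c, hits_n)
  counts$hits_catalytic <- sum(hits_c$passed)
  counts$hits_binding <- sum(hits_n$passed)
  counts$confirmed <- length(confirmed_ids)
  confirmed <- db[db$id %in% confirmed_ids, , drop = FALSE]

  ## --- redundancy + family clustering -------------------------------
  nonred <- removeRedundancy(confirmed, config$dedup_identity)
  counts$nonredundant <- nrow(nonred)
  ## one all-vs-all identity/coverage computation, reused by family
  ## clustering, tree redundancy pruning and the NJ distance matrix
  pm <- pairwiseIdentityMatrix(nonred)
  clusters <- greedySetCoverCluster(nonred, config$cluster_identity,
                                    config$cluster_coverage,
                                    precomputed = pm)
  counts$families <- length(unique(clusters$representative))

  ## --- profile network + MCL ----------------------------------------
  network <- NULL; mcl <- NULL
  if (isTRUE(config$run_network)) {
    reps <- unique(clusters$representative)
    profs <- list()
    for (r in reps) {
      mem <- clusters$member[clusters$representative == r]
      if (length(mem) < config$min_family_size) next
      sub <- nonred[nonred$id %in% mem, , drop = FALSE]
      profs[[r]] <- buildProfile(
        data.frame(id = sub$id, aligned = sub$residues,
                   stringsAsFactors = FALSE),
        name = paste0("fam_", r))
    }
    if (length(profs) >= 1L) {
      network <- buildFamilyNetwork(profs, config$min_probability,
                                    config$network_coverage)
      mcl <- withCallingHandlers(
        mclCluster(network, inflation = config$inflation),
        warning = noteWarn)
      counts$network_families <- length(network@nodes)
      counts$mcl_clusters <- length(unique(mcl$clusters$cluster))
    }
  }

  ## --- pocket classification ----------------------------------------
  pockets <- NULL; tree <- NULL; logos <- NULL
  if (isTRUE(config$run_pockets)) {
    templates <- do.call(rbind, lapply(fams, function(f)
      f$records[1L, , drop = FALSE]))
    modelable <- batchModelingGate(confirmed, templates,
                                   config$modeling_min_identity)
    counts$modelable <- sum(modelable)
    pd <- defaultPocketDefinition()
    fps_true <- truth[match(confirmed$id[modelable], truth$id),
                      c("id", "pocket_residues")]
    names(fps_true) <- c("sequence_id", "residues")
    gen <- generateStructures(fps_true, pd, noise_sd = config$noise_sd,
                              seed = seed + 202L)
    ref <- gen$template
    pockets <- do.call(rbind, lapply(names(gen$structures), function(id)
      extractPocket(gen$structures[[id]], ref, pd,
                    match_cutoff = config$match_cutoff,
                    sequence_id = id)))
    counts$fingerprints <- nrow(pockets)
    tree <- clusterPockets(pockets, config$min_cluster_size,
                           config$cut_height)
    counts$pocket_clusters <- length(unique(tree@assignments$cluster))
    counts$fingerprints_retained <- sum(tree@assignments$retained)
    ## label clusters from one reference member per group
    refs <- setNames(truth$family[match(vapply(fams, function(f)
      f$records$id[1L], character(1L)), truth$id)],
      vapply(fams, function(f) f$records$id[1L], character(1L)))
    grp <- assignGroups(tree, refs)
    tree@assignments$group <- grp
    logos <- lapply(split(pockets, grp[match(pockets$sequence_id,
                                             tree@assignments$sequence_id)]),
                    makeLogo)
  }

  ## --- cofactor prediction ------------------------------------------
  cofactor <- NULL
  if (isTRUE(config$run_cofactor)) {
    aln <- data.frame(id = confirmed$id, aligned = confirmed$residues,
                      stringsAsFactors = FALSE)
    r1 <- unname(specs[[1L]]$cofactor_columns[["R1"]])
    sigs <- extractCofactorWindow(aln, confirmed$id[1L], r1, r1 + 5L)
    gd <- discardGapped(sigs)
    counts$cofactor_input <- nrow(sigs)
    counts$cofactor_retained <- gd$n_retained
    cls <- classifyCofactor(gd$retained$residues)
    cofactor <- gd$retained
    cofactor$predicted_class <- cls
    cofactor <- merge(cofactor, clusterByR1(gd$retained)[
      c("sequence_id", "cluster")], by = "sequence_id")
    counts$cofactor_classified <- sum(cls != "unknown")
  }

  ## --- representative selection --------------------------------------
  selection <- NULL; njt <- NULL
  if (isTRUE(config$run_selection) && !is.null(pockets)) {
    pruned <- removeRedundancy(nonred, config$tree_redundancy_identity,
                               config$tree_redundancy_coverage,
                               precomputed = pm)
    pruned <- pruned[pruned$id %in% pockets$sequence_id, , drop = FALSE]
    counts$tree_taxa <- nrow(pruned)
    if (nrow(pruned) >= 3L) {
      njt <- njTree(identityDistanceMatrix(pruned, precomputed = pm))
      grp_by_id <- setNames(tree@assignments$group,
                            tree@assignments$sequence_id)
      selection <- selectRepresentatives(
        njt, grp_by_id,
        criteria = list(require_p3_glu = TRUE,
                        n_representatives = config$n_representatives,
                        per_group_minimum = config$per_group_minimum),
        fingerprints = pockets)
      counts$selected <- length(selection$selected)
    }
  }

  manifest <- list(config = unclass(config),
                   seeds = c(base = seed, decoys = seed + 101L,
                             structures = seed + 202L),
                   counts = counts, warnings = warnings_log)
  out <- list(db = db, truth = truth, curation = cur, split = dsplit,
              hits_catalytic = hits_c, hits_binding = hits_n,
              confirmed = confirmed, nonredundant = nonred,
              clusters = clusters, network = network, mcl = mcl,
              pockets = pockets, pocket_tree = tree, logos = logos,
              cofactor = cofactor, nj_tree = njt, selection = selection,
              manifest = manifest)
  if (!is.null(outdir)) writeArtifacts(out, outdir)
  out
}

## Derive a sibling group spec: same backbone consensus and planted
## columns, new pocket/cofactor motifs and family id.
variantSpec <- function(spec, family_id, seed, cofactor_class,
                        catalytic = TRUE) {
  v <- spec
  v$family_id <- family_id
  v$seed <- as.integer(seed)
  v$cofactor_class <- cofactor_class
  withSeed(seed, {
    pc <- sample(AA20, 21L, replace = TRUE)
    names(pc) <- paste0("P", 1:21)
    pc[["P3"]] <- if (catalytic) "E" else "A"
    v$consensus[v$pocket_columns] <- pc
    v$consensus[v$cofactor_columns] <- COFACTOR_CONSENSUS[[cofactor_class]]
  })
  v
}

writeArtifacts <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  writeFastaRecords(out$db, p("database.fasta"))
  writeTruthTable(out$truth, p("truth.tsv"))
  writeTsv(out$hits_catalytic, p("hits_catalytic.tsv"))
  writeTsv(out$hits_binding, p("hits_binding.tsv"))
  writeTsv(out$clusters, p("families.tsv"))
  if (!is.null(out$network)) writeTsv(out$network@edges, p("network.tsv"))
  if (!is.null(out$mcl)) writeTsv(out$mcl$clusters, p("mcl_clusters.tsv"))
  if (!is.null(out$pockets)) writeTsv(out$pockets, p("fingerprints.tsv"))
  if (!is.null(out$pocket_tree))
    writeTsv(out$pocket_tree@assignments, p("pocket_clusters.tsv"))
  if (!is.null(out$cofactor)) writeTsv(out$cofactor, p("cofactor.tsv"))
  if (!is.null(out$nj_tree))
    ape::write.tree(out$nj_tree, p("nj_tree.nwk"))
  if (!is.null(out$selection))
    writeTsv(out$selection$report, p("selection.tsv"))
  yaml::write_yaml(out$manifest, p("manifest.yaml"))
  invisible(outdir)
}
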