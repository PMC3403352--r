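#' Pipeline run configuration
#'
#' Bundles all input paths and module parameters. Every parameter has a
#' default except the input paths and the random seed. A config round-trips
#' through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param genome_dir directory of per-genome `<id>.faa` + `<id>.gff3` pairs.
#' @param seeds_fasta FASTA of family seed proteins.
#' @param seed_families_tsv TSV with columns `seed_id`, `family_id`.
#' @param out_dir output directory.
#' @param seed integer root seed (required).
#' @param reference_tree optional Newick species tree path.
#' @param evalue_cutoff homolog retention threshold (default 0.1).
#' @param gap_open,gap_extend,lambda,K alignment and E-value parameters.
#' @param max_gap_bp operon intergenic-gap threshold (default 100).
#' @param rank_window gene-rank window `D` for the neighborhood score.
#' @param anchors trait marker families, in the order ruvA, ruvB, ruvC, recU.
#' @param neighborhood_anchors families whose genes anchor proximity
#'   (default the two resolvases).
#' @param tree_family family whose members are aligned and classified into
#'   subtypes (default `"yebC"`).
#' @param bootstrap_replicates bootstrap replicates for the gene tree.
#' @param max_gap_fraction column-masking threshold before distances.
#' @param strict SDP conservation threshold (default 0.9).
#' @param min_group minimum members per subtype for SDP calling.
#' @param distance_ceiling Kimura-correction overflow distance.
#' @return list of class `run_config`.
#' @export
run_config <- function(genome_dir, seeds_fasta, seed_families_tsv, out_dir,
                       seed, reference_tree = NULL, evalue_cutoff = 0.1,
                       gap_open = 11, gap_extend = 1, lambda = 0.318,
                       K = 0.134, max_gap_bp = 100, rank_window = 3,
                       anchors = c("ruvA", "ruvB", "ruvC", "recU"),
                       neighborhood_anchors = c("ruvC", "recU"),
                       tree_family = "yebC", bootstrap_replicates = 100,
                       max_gap_fraction = 0.5, strict = 0.9, min_group = 3,
                       distance_ceiling = 10) {
  .stop_if(missing(seed) || is.null(seed) || is.na(seed),
           "config requires a seed")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

.artifact <- function(cfg, name) file.path(cfg$out_dir, name)

.need_artifact <- function(cfg, name, producer) {
  p <- .artifact(cfg, name)
  .stop_if(!file.exists(p), "missing artifact '", name,
           "'; run the '", producer, "' stage first")
  p
}

.load_genomes <- function(cfg) {
  faa <- sort(list.files(cfg$genome_dir, pattern = "\\.faa$",
                         full.names = TRUE))
  .stop_if(length(faa) == 0L, "no .faa genomes in ", cfg$genome_dir)
  lapply(faa, function(f)
    read_genome(f, sub("\\.faa$", ".gff3", f)))
}

.load_seeds <- function(cfg) {
  aa <- Biostrings::readAAStringSet(cfg$seeds_fasta)
  seeds <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  fam <- read.delim(cfg$seed_families_tsv, stringsAsFactors = FALSE)
  list(seeds = seeds,
       families = setNames(fam$family_id, fam$seed_id))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Individual pipeline stages
#'
#' Each stage reads the artifacts of earlier stages from `config$out_dir`
#' and writes its own; [run_full()] chains them. They can be invoked
#' independently (the CLI subcommands map onto them) and error with the name
#' of the producing stage when an upstream artifact is missing.
#'
#' @param config a [run_config()].
#' @return invisibly, the paths written.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_homology <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- .load_genomes(config)
  sd <- .load_seeds(config)
  hits <- find_family_members(genomes, sd$seeds, sd$families,
                              evalue_cutoff = config$evalue_cutoff,
                              gap_open = config$gap_open,
                              gap_extend = config$gap_extend,
                              lambda_ = config$lambda, K = config$K)
  invisible(.write_tsv(hits, .artifact(config, "hits.tsv")))
}

#' @rdname pipeline_stages
#' @export
stage_profile <- function(config) {
  hits <- read.delim(.need_artifact(config, "hits.tsv", "homology"),
                     stringsAsFactors = FALSE)
  genomes <- .load_genomes(config)
  sd <- .load_seeds(config)
  om <- assign_orthologs(hits)
  profile <- build_profile(om, genomes,
                           families = sort(unique(unname(sd$families))))
  calls <- call_traits(profile, config$anchors)
  paths <- c(.write_tsv(om, .artifact(config, "orthologs.tsv")),
             write_profile_tsv(profile, .artifact(config, "profile.tsv")),
             .write_tsv(calls, .artifact(config, "trait_calls.tsv")))
  ref <- if (!is.null(config$reference_tree))
    read_newick(config$reference_tree) else NULL
  occ <- occurrence_by_taxon(profile, genomes, ref, calls)
  paths <- c(paths, .write_tsv(occ, .artifact(config, "taxon_occurrence.tsv")))
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_link <- function(config) {
  profile <- read_profile_tsv(.need_artifact(config, "profile.tsv", "profile"))
  om <- read.delim(.need_artifact(config, "orthologs.tsv", "profile"),
                   stringsAsFactors = FALSE)
  calls <- read.delim(.need_artifact(config, "trait_calls.tsv", "profile"),
                      stringsAsFactors = FALSE)
  hits <- read.delim(.need_artifact(config, "hits.tsv", "homology"),
                     stringsAsFactors = FALSE)
  genomes <- .load_genomes(config)
  sd <- .load_seeds(config)
  n_genomes <- length(genomes)

  operons <- list()
  prox <- list()
  candidates <- setdiff(colnames(profile$matrix), config$anchors)
  for (g in genomes) {
    ops <- infer_operons(g, config$max_gap_bp)
    operons[[g$genome_id]] <- ops
    og <- om[om$genome_id == g$genome_id, , drop = FALSE]
    anchor_genes <- og$gene_id[og$family_id %in% config$neighborhood_anchors &
                               og$role == "ortholog"]
    if (length(anchor_genes) == 0L) next
    for (f in candidates) {
      cand_genes <- og$gene_id[og$family_id == f]
      if (length(cand_genes) == 0L) next
      pr <- proximity(g, cand_genes, anchor_genes, ops)
      if (nrow(pr) > 0L) { pr$family_id <- f; prox[[length(prox) + 1L]] <- pr }
    }
  }
  operons <- do.call(rbind, c(operons, list(make.row.names = FALSE)))
  prox <- if (length(prox)) do.call(rbind, prox) else
    data.frame(genome_id = character(), candidate_gene_id = character(),
               anchor_gene_id = character(), distance = integer(),
               same_operon = logical(), same_strand = logical(),
               family_id = character())
  s_nbr <- vapply(candidates, function(f)
    neighborhood_score(prox[prox$family_id == f, , drop = FALSE],
                       n_genomes, config$rank_window), 0)
  seed_lengths <- setNames(nchar(sd$seeds), names(sd$seeds))
  fusions <- detect_fusions(hits, seed_lengths)
  trait <- setNames(as.integer(calls$status %in%
                                 c("RuvABC", "RuvAB+RecU", "both")),
                    calls$genome_id)
  report <- rank_partners(profile, config$anchors, s_nbr, fusions,
                          anchor_presence = trait)
  invisible(c(.write_tsv(operons, .artifact(config, "operons.tsv")),
              .write_tsv(prox, .artifact(config, "proximity.tsv")),
              .write_tsv(report, .artifact(config, "linkage_report.tsv"))))
}

#' @rdname pipeline_stages
#' @export
stage_tree <- function(config) {
  om <- read.delim(.need_artifact(config, "orthologs.tsv", "profile"),
                   stringsAsFactors = FALSE)
  genomes <- .load_genomes(config)
  members <- om[om$family_id == config$tree_family & om$role == "ortholog", ]
  .stop_if(nrow(members) < 3L, "fewer than 3 members of family '",
           config$tree_family, "'; no tree built")
  seqs <- vapply(seq_len(nrow(members)), function(i) {
    g <- genomes[[which(vapply(genomes, function(x) x$genome_id, "") ==
                          members$genome_id[i])]]
    g$genes$protein[g$genes$gene_id == members$gene_id[i]]
  }, "")
  names(seqs) <- members$genome_id
  ali <- progressive_align(seqs, gap_open = config$gap_open,
                           gap_extend = config$gap_extend)
  writeLines(unlist(lapply(rownames(ali), function(id)
    c(paste0(">", id), paste(ali[id, ], collapse = "")))),
    .artifact(config, "aligned.faa"))
  masked <- mask_gappy_columns(ali, config$max_gap_fraction)
  writeLines(as.character(attr(masked, "column_map")),
             .artifact(config, "column_map.txt"))
  tree <- bootstrap_support(masked, config$bootstrap_replicates,
                            seed = stage_seed(config$seed, "bootstrap"),
                            ceiling = config$distance_ceiling)
  ape::write.tree(tree, .artifact(config, "tree.nwk"))
  invisible(c(.artifact(config, "aligned.faa"), .artifact(config, "tree.nwk")))
}

#' @rdname pipeline_stages
#' @export
stage_sdp <- function(config) {
  tree <- read_newick(.need_artifact(config, "tree.nwk", "tree"))
  lines <- readLines(.need_artifact(config, "aligned.faa", "tree"))
  heads <- grep("^>", lines)
  ali <- msa_from_strings(setNames(lines[heads + 1L],
                                   sub("^>", "", lines[heads])))
  cmap <- as.integer(readLines(.need_artifact(config, "column_map.txt",
                                              "tree")))
  masked <- ali[, cmap, drop = FALSE]
  attr(masked, "column_map") <- cmap
  labels <- split_subtypes(tree)
  sdp <- classify_columns(masked, labels, strict = config$strict,
                          min_group = config$min_group)
  paths <- c(.write_tsv(data.frame(genome_id = names(labels),
                                   subtype = unname(labels)),
                        .artifact(config, "subtype_labels.tsv")))
  sdp_report(sdp, masked, .artifact(config, "sdp.tsv"),
             .artifact(config, "sdp_annotated.faa"))
  invisible(c(paths, .artifact(config, "sdp.tsv"),
              .artifact(config, "sdp_annotated.faa")))
}

.RUN_STAGES <- c("homology", "profiles", "trait_calls", "neighborhood",
                 "linkage", "msa", "tree", "subtypes", "sdp")

#' @rdname pipeline_stages
#' @export
stage_report <- function(config) {
  count_rows <- function(name) {
    p <- .artifact(config, name)
    if (!file.exists(p)) return(NA_integer_)
    nrow(read.delim(p, stringsAsFactors = FALSE))
  }
  arts <- c("hits.tsv", "orthologs.tsv", "profile.tsv", "trait_calls.tsv",
            "taxon_occurrence.tsv", "operons.tsv", "proximity.tsv",
            "linkage_report.tsv", "aligned.faa", "column_map.txt", "tree.nwk",
            "subtype_labels.tsv", "sdp.tsv", "sdp_annotated.faa")
  present <- arts[file.exists(file.path(config$out_dir, arts))]
  checksums <- as.list(tools::md5sum(file.path(config$out_dir, present)))
  names(checksums) <- present
  report <- list(
    package_version = as.character(utils::packageVersion("traitscan")),
    seed = config$seed,
    stages = .RUN_STAGES,
    counts = list(hits = count_rows("hits.tsv"),
                  orthologs = count_rows("orthologs.tsv"),
                  genomes = count_rows("trait_calls.tsv"),
                  operons = count_rows("operons.tsv"),
                  proximity = count_rows("proximity.tsv"),
                  linkage_candidates = count_rows("linkage_report.tsv"),
                  sdp_columns = count_rows("sdp.tsv")),
    checksums = checksums)
  jsonlite::write_json(report, .artifact(config, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(.artifact(config, "run_report.json"))
}

#' Run the full pipeline
#'
#' Executes homology search, ortholog assignment and profiling, trait calls,
#' neighborhood analysis, linkage ranking, multiple alignment, tree building
#' with bootstrap, subtype partitioning and SDP detection, in order, writing
#' every artifact plus a machine-readable `run_report.json`. A stage failure
#' aborts the run naming the stage.
#'
#' @param config a [run_config()].
#' @return the parsed run report, invisibly.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run_stage <- function(name, fn) {
    tryCatch(fn(config), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  run_stage("homology", stage_homology)
  run_stage("profile", stage_profile)
  run_stage("link", stage_link)
  run_stage("tree", stage_tree)
  run_stage("sdp", stage_sdp)
  run_stage("report", stage_report)
  invisible(jsonlite::read_json(.artifact(config, "run_report.json")))
}
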