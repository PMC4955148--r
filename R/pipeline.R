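# pipeline: orchestrate the mining workflow (build profile -> scan proteome
# -> tree of top hits -> conservation report -> optional promoter scan) with
# deterministic, manifest-tracked outputs.

#' Mining-pipeline configuration
#'
#' @param training_msa path to the curated training alignment (aligned
#'   FASTA) used to build the profile HMM.
#' @param proteome path to the proteome FASTA to mine.
#' @param out_dir output directory (created if missing).
#' @param hits_msa optional aligned FASTA containing the candidate/top-hit
#'   sequences for the tree and conservation stages; defaults to the
#'   training alignment. The tree uses the rows whose ids rank in the top
#'   hits; if fewer than 3 such rows are present, all rows are used.
#' @param upstream_fasta optional DNA FASTA of upstream/promoter regions;
#'   when given, the promoter scan stage runs.
#' @param anchors optional data frame (or TSV path) of conservation anchors
#'   (see [conservation_report()]).
#' @param evidence optional TSV path with an `id` column; joined onto the
#'   ranking for display, never used to re-rank.
#' @param top_n number of top-scoring proteins to keep (default 15).
#' @param bootstrap bootstrap replicates for the tree (default 100; 0
#'   disables supports and collapsing).
#' @param collapse support threshold below which edges are collapsed
#'   (default 75).
#' @param seed integer seed; required when `bootstrap > 0`.
#' @param hmm an [hmm_config()].
#' @param promoter_motif IUPAC DNA motif for the promoter scan (default the
#'   van Peij XlnR-binding consensus `"GGCTAAA"`).
#' @param promoter_region upstream window length in bases (default 1000).
#' @param map_ambiguous map B/Z/J/U/O to X when reading sequences.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(training_msa, proteome, out_dir,
                            hits_msa = NULL, upstream_fasta = NULL,
                            anchors = NULL, evidence = NULL,
                            top_n = 15L, bootstrap = 100L, collapse = 75,
                            seed = NULL, hmm = hmm_config(),
                            promoter_motif = "GGCTAAA",
                            promoter_region = 1000L,
                            map_ambiguous = FALSE) {
  cfg <- list(training_msa = training_msa, proteome = proteome,
              out_dir = out_dir, hits_msa = hits_msa,
              upstream_fasta = upstream_fasta, anchors = anchors,
              evidence = evidence, top_n = as.integer(top_n),
              bootstrap = as.integer(bootstrap), collapse = collapse,
              seed = if (is.null(seed)) NULL else as.integer(seed),
              hmm = hmm, promoter_motif = promoter_motif,
              promoter_region = as.integer(promoter_region),
              map_ambiguous = isTRUE(map_ambiguous))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an `hmm`
#' block maps to [hmm_config()].
#'
#' @param path YAML config path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  hmm <- if (is.null(y$hmm)) hmm_config() else do.call(hmm_config, y$hmm)
  y$hmm <- NULL
  do.call(pipeline_config, c(y, list(hmm = hmm)))
}

.pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the candidate-transporter mining pipeline
#'
#' Executes profile build, proteome scan (top-N ranking), neighbor-joining
#' tree with bootstrap supports and low-support collapsing over the top
#' hits, a residue-conservation report, and an optional promoter-motif
#' scan. Outputs (`ranking.tsv`, `tree.nwk`, `conservation.tsv`,
#' `promoter_hits.tsv`, `manifest.json`) are byte-identical across runs
#' with the same config and seed. On error the failing stage is named and
#' partial outputs are removed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the ranking, tree, reports and manifest.
#' @export
run_mining_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outputs <- character()
  on_fail <- function(e) {
    unlink(outputs)
    stop(conditionMessage(e), call. = FALSE)
  }
  withCallingHandlers(tryCatch({
    .pipeline_stage("config", {
      for (p in c(config$training_msa, config$proteome, config$hits_msa,
                  config$upstream_fasta))
        if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
      if (config$bootstrap > 0L && is.null(config$seed))
        stop("a seed is required when bootstrap > 0")
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    })
    out <- function(f) file.path(config$out_dir, f)

    msa <- .pipeline_stage("read-training-msa",
      read_alignment(config$training_msa, config$map_ambiguous))
    model <- .pipeline_stage("build-profile", build_profile(msa, config$hmm))
    proteome <- .pipeline_stage("read-proteome",
      read_fasta(config$proteome, config$map_ambiguous))
    ranking <- .pipeline_stage("scan-proteome",
      scan_proteome(model, proteome, config$top_n))
    if (!is.null(config$evidence)) {
      ev <- .pipeline_stage("join-evidence", {
        e <- read.table(config$evidence, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
        if (!"id" %in% names(e)) stop("evidence table needs an id column")
        e
      })
      ranking <- merge(ranking, ev, by = "id", all.x = TRUE, sort = FALSE)
      ranking <- ranking[order(ranking$rank),
                         union(c("rank", "id", "bits"), names(ranking))]
    }
    outputs <- c(outputs, .pipeline_stage("write-ranking",
      .write_tsv(ranking, out("ranking.tsv"))))

    hits_msa <- if (is.null(config$hits_msa)) msa else
      .pipeline_stage("read-hits-msa",
        read_alignment(config$hits_msa, config$map_ambiguous))
    tree <- .pipeline_stage("tree", {
      keep <- hits_msa$id %in% ranking$id
      sub <- if (sum(keep) >= 3L)
        aa_msa(hits_msa$id[keep], hits_msa$seq[keep], hits_msa$desc[keep])
      else hits_msa
      if (length(sub$id) < 3L)
        stop("need at least 3 aligned candidates for a tree")
      if (config$bootstrap > 0L) {
        tr <- bootstrap_support(sub, config$bootstrap, config$seed)
        collapse_low_support(tr, config$collapse)
      } else neighbor_joining(pairwise_distances(sub))
    })
    outputs <- c(outputs, .pipeline_stage("write-tree",
      write_newick(tree, out("tree.nwk"))))

    conservation <- NULL
    if (!is.null(config$anchors)) {
      conservation <- .pipeline_stage("conservation", {
        anc <- if (is.character(config$anchors))
          read.table(config$anchors, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE) else config$anchors
        conservation_report(hits_msa, anc)
      })
      outputs <- c(outputs, .pipeline_stage("write-conservation",
        .write_tsv(conservation, out("conservation.tsv"))))
    }

    promoter <- NULL
    if (!is.null(config$upstream_fasta)) {
      promoter <- .pipeline_stage("promoter-scan", {
        set <- Biostrings::readDNAStringSet(config$upstream_fasta)
        regions <- setNames(as.character(set),
                            .parse_fasta_names(names(set))$id)
        scan_promoters(regions, config$promoter_motif,
                       config$promoter_region)
      })
      outputs <- c(outputs, .pipeline_stage("write-promoter",
        .write_tsv(promoter, out("promoter_hits.tsv"))))
    }

    manifest <- .pipeline_stage("manifest", {
      inputs <- Filter(Negate(is.null),
                       list(training_msa = config$training_msa,
                            proteome = config$proteome,
                            hits_msa = config$hits_msa,
                            upstream_fasta = config$upstream_fasta))
      man <- list(
        tool = "spminer",
        version = as.character(utils::packageVersion("spminer")),
        seed = config$seed,
        config = .echo_config(config),
        inputs = lapply(inputs, function(p)
          list(path = p, md5 = unname(tools::md5sum(p)))),
        outputs = lapply(setNames(outputs, basename(outputs)), function(p)
          list(path = p, md5 = unname(tools::md5sum(p)))))
      jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      man
    })
    outputs <- c(outputs, out("manifest.json"))
    invisible(list(ranking = ranking, tree = tree,
                   conservation = conservation, promoter = promoter,
                   manifest = manifest, outputs = outputs))
  }, error = on_fail))
}

.echo_config <- function(config) {
  cfg <- unclass(config)
  cfg$hmm <- unclass(cfg$hmm)
  if (is.data.frame(cfg$anchors)) cfg$anchors <- "<inline data frame>"
  Filter(Negate(is.null), cfg)
}
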