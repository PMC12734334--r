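#' Assemble and validate a pipeline run configuration
#'
#' @param fasta Optional FASTA path for the mining stage.
#' @param genotypes,manifest Paths to a genotype table and marker manifest;
#'   if omitted, a synthetic population is generated from
#'   \code{\link{population_spec}} defaults under \code{seed}.
#' @param metadata Path to a trait/origin table; if omitted, synthetic
#'   metadata is generated.
#' @param codebook Path to a codebook file; default
#'   \code{\link{default_codebook}}.
#' @param mining_rules A \code{\link{motif_rules}}.
#' @param cut Similarity threshold for group assignment, in [0, 1].
#' @param core_target Optional core size passed to
#'   \code{\link{select_core}}.
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Output directory (created if absent).
#' @return Validated list of class \code{run_config}.
#' @export
run_config <- function(fasta = NULL, genotypes = NULL, manifest = NULL,
                       metadata = NULL, codebook = NULL,
                       mining_rules = motif_rules(), cut = 0.76,
                       core_target = NULL, seed = 1L, out_dir = "ssrcore-run") {
  for (f in c(fasta, genotypes, manifest, metadata, codebook))
    if (!is.null(f) && !file.exists(f))
      stop("missing input: ", f)
  if (!is.null(genotypes) && is.null(manifest))
    stop("a marker manifest is required alongside a genotype table")
  if (cut < 0 || cut > 1) stop("parameter out of range: cut must be in [0,1]")
  structure(list(fasta = fasta, genotypes = genotypes, manifest = manifest,
                 metadata = metadata, codebook = codebook,
                 mining_rules = mining_rules, cut = cut,
                 core_target = core_target, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full characterization pipeline
#'
#' Executes, in dependency order: SSR mining (when a FASTA is supplied),
#' per-locus diversity statistics, simple-matching similarity and UPGMA
#' clustering with a threshold cut, M-strategy core selection, and molecular
#' identity codes. Writes every stage output under one directory plus a JSON
#' manifest (parameter echo, stage file list, md5 checksums) sufficient to
#' verify a bit-identical re-run.
#'
#' @param config A \code{\link{run_config}}.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(path) outputs <<- c(outputs, path)

  if (!is.null(config$fasta)) {
    stage("mine", {
      catalog <- find_ssrs(config$fasta, config$mining_rules)
      emit(write_locus_table(catalog, file.path(config$out_dir, "loci.tsv")))
      emit(write_catalog_gff3(catalog, file.path(config$out_dir,
                                                 "loci.gff3")))
      comp <- summarize_catalog(catalog)
      emit(file.path(config$out_dir, "composition.tsv"))
      utils::write.table(comp$by_motif_class,
                         file.path(config$out_dir, "composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  sim <- NULL
  g <- stage("genotypes", {
    if (!is.null(config$genotypes)) {
      read_genotypes(config$genotypes,
                     read_marker_manifest(config$manifest))
    } else {
      sim <- simulate_population(population_spec(seed = config$seed))
      sim$genotypes
    }
  })

  stage("stats", {
    tab <- diversity_table(g)
    emit(write_diversity_table(tab, file.path(config$out_dir,
                                              "diversity.tsv")))
  })

  b <- to_band_matrix(g)
  tree <- NULL
  stage("cluster", {
    s <- simple_matching(b)
    emit(write_similarity(s, file.path(config$out_dir, "similarity.tsv")))
    tree <- upgma(s)
    emit(write_newick(tree, file.path(config$out_dir, "tree.nwk")))
    grp <- cut_at_similarity(tree, config$cut)
    emit(file.path(config$out_dir, "groups.tsv"))
    utils::write.table(data.frame(accession = names(grp), group = grp),
                       file.path(config$out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("core", {
    core <- select_core(b, target_size = config$core_target)
    emit(file.path(config$out_dir, "core.tsv"))
    utils::write.table(data.frame(rank = seq_along(core$selected),
                                  accession = core$selected,
                                  coverage = core$coverage_curve),
                       file.path(config$out_dir, "core.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("id", {
    cb <- if (is.null(config$codebook)) default_codebook()
          else read_codebook(config$codebook)
    meta <- if (!is.null(config$metadata)) {
      utils::read.table(config$metadata, header = TRUE, sep = ",",
                        stringsAsFactors = FALSE)
    } else {
      simulate_traits(nrow(b), cb,
                      groups = if (!is.null(sim)) sim$truth$groups,
                      seed = config$seed)
    }
    ids <- molecular_id_table(b, meta, cb)
    emit(write_molecular_ids(ids, file.path(config$out_dir, "ids.tsv")))
  })

  manifest <- list(
    package = "ssrcore",
    version = as.character(utils::packageVersion("ssrcore")),
    parameters = list(cut = config$cut, core_target = config$core_target,
                      seed = config$seed,
                      mining_thresholds = as.list(
                        stats::setNames(as.integer(config$mining_rules),
                                        names(config$mining_rules))),
                      inputs = list(fasta = config$fasta,
                                    genotypes = config$genotypes,
                                    metadata = config$metadata)),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
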