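# end-to-end pipeline: simulate -> trim -> screen -> cluster -> orfgc ->
# snps -> dde -> enrich, with manifest and per-stage seed substreams

.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(n_genes = 100, gc3_modes = list(c(0.45, 1.0)),
                    n_paralog_pairs = 0, n_allelic_variants = 0,
                    n_dev = 2, n_stress = 2, n_de = 10, fold = 5,
                    n_reads = 400, adapter = "", with_qualities = FALSE),
    trim = list(min_length = 100, polya_min_run = 8, quality_floor = 15,
                window = 10),
    screen = list(hits_file = NULL, evalue_cut = 1e-40, identity_cut = 80),
    cluster = list(min_identity = 0.90, min_overlap = 40),
    snp = list(min_reads = 4, min_allele_support = 2, confidence_floor = 0.2,
               paralog_divergence_cut = 3),
    dde = list(alpha = 0.05, min_library_ests = 300, min_contig_ests = 3),
    enrich = list(family_matrix = NULL, focal = NULL),
    counts_file = NULL
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full EST mining pipeline
#'
#' Executes simulation (or ingestion), trimming, contaminant screening,
#' clustering, CDS/GC annotation, SNP detection, differential expression
#' and enrichment in order, writing per-stage artifacts and a JSON
#' manifest (parameters, seed, file checksums) to \code{outDir}.  A
#' stage is skipped when its input is supplied directly: providing
#' \code{counts_file} jumps straight to the expression stage, and the
#' screening stage only runs when a similarity hit file is configured.
#' The global seed is expanded into per-stage substreams so stage-level
#' reruns are reproducible in isolation.
#'
#' @param config Configuration list or path to a YAML file; unset fields
#'   fall back to defaults (see the package vignette).
#' @param outDir Output directory.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("estmine")),
                   seed = cfg$seed, parameters = cfg, stages = list())
  results <- list()
  record <- function(stage, files) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  }

  counts <- NULL
  libLevels <- NULL

  if (!is.null(cfg$counts_file)) {
    counts <- as.matrix(utils::read.table(cfg$counts_file, sep = "\t",
                                          header = TRUE, row.names = 1,
                                          check.names = FALSE))
    manifest$stages$simulate <- list(skipped = "counts supplied directly")
  } else {
    sc <- cfg$simulate
    gc3 <- do.call(rbind, lapply(sc$gc3_modes, as.numeric))
    tx <- generateTranscriptome(
      nGenes = sc$n_genes, gc3Modes = gc3,
      nParalogPairs = sc$n_paralog_pairs,
      nAllelicVariants = sc$n_allelic_variants,
      seed = substreamSeed(cfg$seed, "simulate"))
    dz <- conditionDesigns(tx$genes, nDev = sc$n_dev, nStress = sc$n_stress,
                           nDe = sc$n_de, fold = sc$fold,
                           nReads = sc$n_reads,
                           seed = substreamSeed(cfg$seed, "designs"))
    sim <- simulateEstLibraries(tx$genes, dz$designs,
                                adapter = sc$adapter,
                                withQualities = isTRUE(sc$with_qualities),
                                seed = substreamSeed(cfg$seed, "reads"))
    writeSimulation(sim, outDir)
    results$transcriptome <- tx
    results$simulation <- sim
    record("simulate", file.path(outDir, c("reads.fasta", "reads.fastq",
                                           "library_table.tsv", "truth.json")))

    tr <- trimReads(sim$ests, adapter = if (nzchar(sc$adapter)) sc$adapter
                    else NULL,
                    minLength = cfg$trim$min_length,
                    polyaMinRun = cfg$trim$polya_min_run,
                    qualityFloor = cfg$trim$quality_floor,
                    window = cfg$trim$window)
    writeXStringSet(estSequences(tr$ests), file.path(outDir, "trimmed.fasta"))
    writeTsv(tr$rejected, file.path(outDir, "rejected.tsv"))
    results$trimmed <- tr
    record("trim", file.path(outDir, c("trimmed.fasta", "rejected.tsv")))

    contigs <- clusterEsts(tr$ests,
                           minIdentity = cfg$cluster$min_identity,
                           minOverlap = cfg$cluster$min_overlap)

    if (!is.null(cfg$screen$hits_file)) {
      hits <- readBlastTab(cfg$screen$hits_file)
      ids <- c(names(contigConsensus(contigs)),
               names(contigSinglets(contigs)))
      scr <- screenContaminants(ids, hits,
                                evalueCut = cfg$screen$evalue_cut,
                                identityCut = cfg$screen$identity_cut)
      results$screen <- scr
      writeTsv(data.frame(cluster_id = scr$contaminant),
               file.path(outDir, "contaminant_clusters.tsv"))
      record("screen", file.path(outDir, "contaminant_clusters.tsv"))
    } else {
      manifest$stages$screen <- list(skipped = "no similarity hit file")
    }

    writeXStringSet(contigConsensus(contigs),
                    file.path(outDir, "contigs.fasta"))
    memb <- do.call(rbind, lapply(seq_along(contigMembers(contigs)),
      function(i) cbind(contig_id = names(contigConsensus(contigs))[i],
                        contigMembers(contigs)[[i]])))
    if (!is.null(memb)) writeTsv(memb, file.path(outDir, "membership.tsv"))
    results$contigs <- contigs
    libMap <- estLibraries(tr$ests)
    libLevels <- sort(unique(unname(estLibraries(sim$ests))))
    counts <- buildCountMatrix(contigs, libMap, libLevels = libLevels)
    utils::write.table(counts, file.path(outDir, "counts.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    record("cluster", file.path(outDir, c("contigs.fasta", "membership.tsv",
                                          "counts.tsv")))

    ann <- annotateCds(contigs)
    writeTsv(ann$annotations, file.path(outDir, "cds_annotations.tsv"))
    if (!is.null(ann$gc3_histogram))
      writeTsv(data.frame(mid = ann$gc3_histogram$mids,
                          raw = ann$gc3_histogram$raw,
                          smoothed = ann$gc3_histogram$smoothed),
               file.path(outDir, "gc3_histogram.tsv"))
    results$annotations <- ann
    record("orfgc", file.path(outDir, c("cds_annotations.tsv",
                                        "gc3_histogram.tsv")))

    snpCalls <- NULL
    screened <- numeric(0)
    consAll <- contigConsensus(contigs)
    for (cid in names(consAll)) {
      al <- contigAlignment(contigs, cid, tr$ests)
      if (nrow(al$aln) < cfg$snp$min_reads) next
      det <- detectSnps(al, minReads = cfg$snp$min_reads,
                        minAlleleSupport = cfg$snp$min_allele_support,
                        confidenceFloor = cfg$snp$confidence_floor,
                        paralogDivergenceCut = cfg$snp$paralog_divergence_cut)
      if (det$paralog_flag) next  # collapsed paralogs excluded from summaries
      screened[cid] <- ncol(al$aln)
      if (nrow(det$calls) > 0L) {
        cons <- as.character(consAll[[cid]])
        a <- ann$annotations[ann$annotations$id == cid, ]
        det$calls <- labelSynonymy(det$calls, a, cons)
        snpCalls <- rbind(snpCalls,
                          cbind(contig_id = cid, det$calls,
                                ref = vapply(det$calls$position + 1L,
                                             function(p) substr(cons, p, p),
                                             character(1))))
      }
    }
    if (!is.null(snpCalls)) {
      out <- snpCalls
      out$pos <- out$position + 1L  # 1-based on output, VCF convention
      writeTsv(out[, c("contig_id", "pos", "ref", "alleles", "allelic_class",
                       "mutation_class", "synonymy", "confidence")],
               file.path(outDir, "snp_calls.tsv"))
    }
    results$snp_calls <- snpCalls
    if (length(screened)) {
      results$snp_summary <- summarizeSnps(
        if (is.null(snpCalls))
          data.frame(contig_id = character(0),
                     mutation_class = character(0),
                     allelic_class = character(0)) else snpCalls,
        screened)
      jsonlite::write_json(results$snp_summary,
                           file.path(outDir, "snp_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    record("snp", file.path(outDir, c("snp_calls.tsv", "snp_summary.json")))
  }

  de <- selectDeContigs(counts, deConfig(
    alpha = cfg$dde$alpha,
    minLibraryEsts = cfg$dde$min_library_ests,
    minContigEsts = cfg$dde$min_contig_ests))
  writeTsv(de, file.path(outDir, "de_results.tsv"))
  results$de <- de
  if (nrow(de) >= 2L) {
    pc <- profileCluster(attr(de, "profiles"))
    results$profile_cluster <- pc
    ape::write.tree(ape::as.phylo(pc$hclust),
                    file.path(outDir, "dendrogram.nwk"))
    utils::write.table(pc$matrix, file.path(outDir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    grDevices::png(file.path(outDir, "heatmap.png"), width = 640,
                   height = 640)
    graphics::image(t(pc$matrix[rev(seq_len(nrow(pc$matrix))), ,
                                drop = FALSE]),
                    col = grDevices::gray(seq(1, 0, length.out = 64)),
                    axes = FALSE,
                    main = "relative transcript abundance (black = high)")
    grDevices::dev.off()
  }
  record("dde", file.path(outDir, c("de_results.tsv", "dendrogram.nwk",
                                    "profiles.tsv", "heatmap.png")))

  if (!is.null(cfg$enrich$family_matrix)) {
    fm <- readFamilyMatrix(cfg$enrich$family_matrix)
    fam <- familyPrevalenceScreen(fm, cfg$enrich$focal)
    writeTsv(fam, file.path(outDir, "family_labels.tsv"))
    results$families <- fam
    record("enrich", file.path(outDir, "family_labels.tsv"))
  } else {
    manifest$stages$enrich <- list(skipped = "no family matrix configured")
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
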