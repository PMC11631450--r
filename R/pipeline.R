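#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Only the
#' stages named in `stages` run, in the fixed order curate, evidence,
#' subset, rename, orthostats, haplobin, stats. Every referenced input path
#' is checked before any stage runs.
#'
#' @param gff,repeatsBed,rnaBed,proteinBed Input annotation and track
#'   paths.
#' @param functionalIdsFile,orthogroupIdsFile Plain-text gene id lists
#'   (one id per line) from external functional-annotation and orthogroup
#'   classification runs.
#' @param orthogroupTables Named character vector of two-column
#'   gene/orthogroup TSV paths, one per genome.
#' @param genomeFasta Assembly FASTA for the stats stage.
#' @param parentAFasta,parentBFasta,scaffoldsFasta FASTAs for the haplobin
#'   stage.
#' @param outDir Output directory (created if needed).
#' @param stages Character vector of stage names to run.
#' @param repeatFractionThreshold,subsetLevel,k,minMargin,minCount,tolPrefix,cultivar,version,unplacedToken
#'   Stage parameters (see the stage functions).
#' @param chromMap Named character vector seqname -> chromosome token for
#'   the rename stage; when `NULL`, tokens `ch01`, `ch02`, ... are assigned
#'   to seqnames in sorted order.
#' @param seed Seed echoed into the report (stages themselves are
#'   deterministic).
#' @return Validated configuration list.
#' @export
pipelineConfig <- function(gff = NULL, repeatsBed = NULL, rnaBed = NULL,
                           proteinBed = NULL, functionalIdsFile = NULL,
                           orthogroupIdsFile = NULL, orthogroupTables = NULL,
                           genomeFasta = NULL, parentAFasta = NULL,
                           parentBFasta = NULL, scaffoldsFasta = NULL,
                           outDir = tempfile("orchardqc_run_"),
                           stages = character(),
                           repeatFractionThreshold = 0.90, subsetLevel = 3L,
                           k = 21L, minMargin = 0.02, minCount = 1000L,
                           tolPrefix = "drMalDome", cultivar = "wa38",
                           version = "v1a1", chromMap = NULL,
                           unplacedToken = "chun", seed = 1L) {
  known <- c("curate", "evidence", "subset", "rename", "orthostats",
             "haplobin", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  as.list(environment())[setdiff(names(formals(pipelineConfig)), "known")]
}

.md5 <- function(paths) {
  unname(tools::md5sum(unlist(paths, use.names = FALSE)))
}

#' Run the curation-to-QC pipeline
#'
#' Executes the requested stages in order (curate, evidence, subset,
#' rename, orthostats, haplobin, stats), logging inputs, parameters and
#' output digests into a JSON report. Any stage failure aborts with the
#' failing stage named and leaves a `PIPELINE_FAILED` marker file next to
#' the partial outputs. Two runs with identical configuration and inputs
#' produce identical report digests.
#'
#' @param config Output of [pipelineConfig()].
#' @return The report, invisibly (also written to
#'   `file.path(config$outDir, "report.json")`).
#' @export
runPipeline <- function(config) {
  needPath <- function(stage) switch(stage,
    curate = c(config$gff, config$repeatsBed),
    evidence = c(config$rnaBed, config$proteinBed),
    subset = NULL,
    rename = NULL,
    orthostats = unname(config$orthogroupTables),
    haplobin = c(config$parentAFasta, config$parentBFasta,
                 config$scaffoldsFasta),
    stats = config$genomeFasta)
  wanted <- as.character(unique(unlist(lapply(config$stages, needPath))))
  missing <- wanted[!file.exists(wanted)]
  if (length(missing)) {
    stop("missing input paths: ", paste(missing, collapse = ", "))
  }
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = config[!vapply(config, is.null, logical(1))],
                 stages = list())
  annotation <- NULL
  flags <- NULL
  order <- c("curate", "evidence", "subset", "rename", "orthostats",
             "haplobin", "stats")
  for (stage in intersect(order, config$stages)) {
    res <- tryCatch(switch(stage,
      curate = {
        annotation <- readGFF3(config$gff)
        repeats <- if (is.null(config$repeatsBed)) {
          GenomicRanges::GRanges()
        } else {
          readRepeatsBed(config$repeatsBed)
        }
        cur <- curateAnnotation(annotation, repeats,
          curationConfig(config$repeatFractionThreshold))
        annotation <- cur$annotation
        out <- file.path(config$outDir, "curated.gff3")
        writeGFF3(annotation, out)
        rep <- file.path(config$outDir, "curation_report.tsv")
        write.table(curationSummary(cur$report), rep, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        list(outputs = c(out, rep))
      },
      evidence = {
        if (is.null(annotation)) annotation <- readGFF3(config$gff)
        readIds <- function(p) if (is.null(p)) character() else readLines(p)
        flags <- computeSupport(annotation,
          rna = readCoverageBed(config$rnaBed),
          protein = readCoverageBed(config$proteinBed),
          functionalIds = readIds(config$functionalIdsFile),
          orthogroupIds = readIds(config$orthogroupIdsFile))
        out <- file.path(config$outDir, "flags.tsv")
        writeSupportFlags(flags, out)
        list(outputs = out)
      },
      subset = {
        if (is.null(flags)) stop("subset requires the evidence stage")
        ids <- selectSubset(flags, config$subsetLevel)
        out <- file.path(config$outDir,
                         paste0("subset", config$subsetLevel, ".txt"))
        writeLines(ids, out)
        list(outputs = out, n = length(ids))
      },
      rename = {
        if (is.null(annotation)) annotation <- readGFF3(config$gff)
        cm <- config$chromMap
        if (is.null(cm)) {
          sq <- sort(unique(as.character(
            GenomicRanges::seqnames(genes(annotation)))))
          cm <- setNames(sprintf("ch%02d", seq_along(sq)), sq)
        }
        rn <- renameAnnotation(annotation, config$tolPrefix, config$cultivar,
                               config$version, cm,
                               unplacedToken = config$unplacedToken)
        annotation <- rn$annotation
        out <- file.path(config$outDir, "renamed.gff3")
        writeGFF3(annotation, out)
        mapf <- file.path(config$outDir, "idmap.tsv")
        write.table(rn$map, mapf, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        list(outputs = c(out, mapf))
      },
      orthostats = {
        tabs <- lapply(config$orthogroupTables, readOrthogroupAssignment)
        mat <- buildCrogMatrix(tabs)
        zres <- zscoreNormalize(mat)
        up <- upsetCounts(lapply(tabs, function(v) unique(unname(v))))
        matf <- file.path(config$outDir, "crog_counts.tsv")
        write.table(mat, matf, sep = "\t", quote = FALSE)
        zf <- file.path(config$outDir, "crog_zscores.tsv")
        write.table(round(zres$z, 6), zf, sep = "\t", quote = FALSE)
        df <- file.path(config$outDir, "crog_dropped.txt")
        writeLines(zres$dropped, df)
        uf <- file.path(config$outDir, "upset_counts.tsv")
        write.table(up, uf, sep = "\t", quote = FALSE, row.names = FALSE)
        list(outputs = c(matf, zf, df, uf))
      },
      haplobin = {
        readFa <- function(p) {
          x <- Biostrings::readDNAStringSet(p)
          setNames(as.character(x), sub(" .*", "", names(x)))
        }
        mA <- canonicalKmers(readFa(config$parentAFasta), k = config$k)
        mB <- canonicalKmers(readFa(config$parentBFasta), k = config$k)
        calls <- assignHaplomes(readFa(config$scaffoldsFasta), mA, mB,
                                minMargin = config$minMargin,
                                minCount = config$minCount)
        out <- file.path(config$outDir, "haplobin.tsv")
        write.table(calls, out, sep = "\t", quote = FALSE, row.names = FALSE)
        list(outputs = out)
      },
      stats = {
        seqs <- Biostrings::readDNAStringSet(config$genomeFasta)
        st <- assemblyStats(seqs)
        telo <- telomereScan(seqs)
        sf <- file.path(config$outDir, "assembly_stats.tsv")
        write.table(as.data.frame(st), sf, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        tf <- file.path(config$outDir, "telomeres.tsv")
        write.table(telo, tf, sep = "\t", quote = FALSE, row.names = FALSE)
        list(outputs = c(sf, tf))
      }),
      error = function(e) {
        marker <- file.path(config$outDir, "PIPELINE_FAILED")
        writeLines(paste0(stage, ": ", conditionMessage(e)), marker)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    res$digests <- setNames(.md5(res$outputs), basename(unlist(res$outputs)))
    report$stages[[stage]] <- res
  }
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
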