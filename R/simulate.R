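# run code under a temporary RNG state so generators are pure given a seed
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

.randomSeq <- function(n, gc = 0.38) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  intToUtf8(sample(utf8ToInt("ACGT"), n, replace = TRUE, prob = p))
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

.mutateSeq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- utf8ToInt(s)
  idx <- which(stats::runif(length(v)) < rate)
  if (length(idx)) {
    # substitute with one of the three other bases, uniformly
    bases <- utf8ToInt("ACGT")
    cur <- match(v[idx], bases)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    v[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  intToUtf8(v)
}

#' Fixture generator configuration
#'
#' Study conditions for the synthetic-data generators. The defaults model a
#' diploid apple-like setting at desk scale: a 38% GC background (the GC
#' content typical of pome fruit sequencing reads), a parental divergence of
#' 1.35% (the heterozygosity expected of an outbred apple cultivar), the
#' 7-mer plant telomere unit, and a small plastome with the canonical
#' quadripartite layout.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param nChromosomes,chromosomeLength Genome shape for
#'   [simulateAnnotatedGenome()] (2 x 100 kb by default).
#' @param nGenes Total number of emitted genes, planted error genes
#'   included (type-2 pairs contribute two genes each).
#' @param nType1,nNearMiss,nType2,nType3 Planted curation errors: type-1
#'   genes (coding region fully inside a planted repeat), near-misses
#'   (repeat overlap fraction ~0.80, below the 0.90 threshold), type-2
#'   pairs (a shorter same-strand overlapper planted next to a normal
#'   gene; `nType2` counts the genes to be removed) and type-3 genes (two
#'   disjoint isoform clusters).
#' @param supportFull,supportAnyOnly Fractions of genes given full /
#'   partial-only evidence coverage (the remainder get none); realized
#'   exactly via rounded counts.
#' @param functionalFraction,orthogroupFraction Fractions of genes put on
#'   the functional-annotation and orthogroup id lists.
#' @param nOrthoGenomes,nSharedOg,nPairOg,nUniqueOg Sharing design for
#'   [simulateOrthogroupTables()]: orthogroups present in all genomes, in
#'   consecutive genome pairs, and unique per genome.
#' @param crossChromosomes,crossLength,divergence,childErrorRate Conditions
#'   for [simulateCross()]: 10 chromosomes x 200 kb, parents diverged by
#'   substitution at rate 0.0135, child haplomes copied from one parent
#'   each with a 0.001 residual error rate.
#' @param telomereUnit,telomereCopies Telomere tandem unit planted at both
#'   ends of every simulated chromosome (reverse complement at the 3' end).
#' @param plastomeLsc,plastomeSsc,plastomeIr Region lengths for
#'   [simulatePlastome()].
#' @param plastomeCategories Named integer vector of organelle feature
#'   counts per category.
#' @param gc Background GC fraction.
#' @return Named list of validated parameters.
#' @export
fixtureConfig <- function(seed = 1L,
                          nChromosomes = 2L, chromosomeLength = 100000L,
                          nGenes = 20L,
                          nType1 = 3L, nNearMiss = 2L, nType2 = 2L,
                          nType3 = 1L,
                          supportFull = 0.6, supportAnyOnly = 0.3,
                          functionalFraction = 0.9,
                          orthogroupFraction = 0.85,
                          nOrthoGenomes = 3L, nSharedOg = 30L, nPairOg = 5L,
                          nUniqueOg = 4L,
                          crossChromosomes = 10L, crossLength = 200000L,
                          divergence = 0.0135, childErrorRate = 0.001,
                          telomereUnit = "AAACCCT", telomereCopies = 100L,
                          plastomeLsc = 10000L, plastomeSsc = 4000L,
                          plastomeIr = 1500L,
                          plastomeCategories = c(rRNA = 4L, tRNA = 20L,
                                                 protein_coding = 40L),
                          gc = 0.38) {
  cfg <- as.list(environment())
  stopifnot(nGenes >= nType1 + nNearMiss + 2L * nType2 + nType3,
            supportFull >= 0, supportAnyOnly >= 0,
            supportFull + supportAnyOnly <= 1,
            divergence >= 0, divergence <= 1,
            childErrorRate >= 0, childErrorRate <= 1,
            nchar(telomereUnit) >= 2,
            plastomeLsc > 0, plastomeSsc > 0, plastomeIr > 0)
  cfg
}

# gene slot geometry used by simulateAnnotatedGenome (1-based coordinates);
# all planted intervals stay within [S, S + 2400] of a slot, so slots are
# mutually isolated at this pitch
.SLOT_PITCH <- 4500L
.SLOT_FIRST <- 3000L

#' Simulate an annotated genome with planted curation errors
#'
#' Emits a random genome, a gene annotation with planted type-1/2/3 error
#' genes (and near-miss repeat-overlap genes that must survive the type-1
#' filter), a repeat track, RNA and protein evidence tracks realizing the
#' configured support proportions exactly, orthogroup assignment tables,
#' and a machine-readable truth record for every planted feature. Telomere
#' tandem arrays are planted at both ends of every chromosome (the reverse
#' complement of the unit at the 3' end). Deterministic for a fixed seed.
#'
#' Support roles are assigned per gene slot (the two genes of a planted
#' type-2 pair always share a role) so that evidence intervals of one gene
#' can never leak support onto a gene with a different planted role.
#'
#' @param config Output of [fixtureConfig()].
#' @param outDir Optional directory; when given, genome FASTA, GFF3, BED
#'   tracks, orthogroup TSVs and a JSON truth record are written there.
#' @return List with `genome` (named character vector), `annotation`
#'   ([GeneAnnotation-class]), `repeats` (`GRanges`), `rna`, `protein`
#'   (`GRanges`), `orthogroups` (named list of assignment vectors),
#'   `orthogroupTruth`, `functionalIds`, `orthogroupIds`, `truth` (list),
#'   and `files` (paths, when written).
#' @export
simulateAnnotatedGenome <- function(config = fixtureConfig(), outDir = NULL) {
  .withSeed(config$seed, {
    nChr <- config$nChromosomes
    chrLen <- config$chromosomeLength
    nGenes <- config$nGenes
    nSlots <- nGenes - config$nType2  # a type-2 slot holds two genes
    perChr <- ceiling(nSlots / nChr)
    teloLen <- nchar(config$telomereUnit) * config$telomereCopies
    need <- .SLOT_FIRST + perChr * .SLOT_PITCH + 1000L + teloLen
    if (need > chrLen) {
      stop("sizing error: ", nGenes, " genes do not fit on ", nChr, " x ",
           chrLen, " bp chromosomes (need ", need, " bp per chromosome)")
    }
    chrNames <- sprintf("chr%02d", seq_len(nChr))
    telo <- strrep(config$telomereUnit, config$telomereCopies)
    genome <- setNames(vapply(chrNames, function(cn) {
      mid <- .randomSeq(chrLen - 2L * teloLen, gc = config$gc)
      paste0(telo, mid, .revcomp(telo))
    }, character(1)), chrNames)

    slotChr <- rep(chrNames, each = perChr)[seq_len(nSlots)]
    slotIdx <- stats::ave(seq_len(nSlots), slotChr, FUN = seq_along)
    slotStart <- .SLOT_FIRST + (slotIdx - 1L) * .SLOT_PITCH

    roles <- rep("normal", nSlots)
    planted <- c(rep("type1", config$nType1), rep("nearmiss", config$nNearMiss),
                 rep("type2", config$nType2), rep("type3", config$nType3))
    roles[seq_along(planted)] <- planted
    roles <- roles[sample.int(nSlots)]  # seeded shuffle over slots

    txList <- list()
    exonsList <- list()
    cdsList <- list()
    repeatRows <- list()
    truth <- list(type1 = character(), nearMiss = character(),
                  type2Removed = character(), type2Partner = character(),
                  type3 = character())
    slotGenes <- vector("list", nSlots)  # gene ids per slot
    geneIdx <- 0L
    addTx <- function(id, gid, chr, strand, exons, cds) {
      gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(min(exons[, 1L]),
                                                         max(exons[, 2L])),
                                   strand = strand)
      names(gr) <- id
      gr$gene_id <- gid
      txList[[id]] <<- gr
      exonsList[[id]] <<- GenomicRanges::GRanges(
        chr, IRanges::IRanges(exons[, 1L], exons[, 2L]), strand = strand)
      cdsList[[id]] <<- GenomicRanges::GRanges(
        chr, IRanges::IRanges(cds[, 1L], cds[, 2L]), strand = strand)
    }

    for (i in seq_len(nSlots)) {
      geneIdx <- geneIdx + 1L
      gid <- sprintf("gene%03d", geneIdx)
      chr <- slotChr[i]
      S <- slotStart[i]
      strand <- if (i %% 2L) "+" else "-"
      role <- roles[i]
      slotGenes[[i]] <- gid
      if (role == "type3") {
        addTx(paste0(gid, ".t1"), gid, chr, strand,
              exons = rbind(c(S, S + 600L)), cds = rbind(c(S + 100L, S + 500L)))
        addTx(paste0(gid, ".t2"), gid, chr, strand,
              exons = rbind(c(S + 2200L, S + 2800L)),
              cds = rbind(c(S + 2300L, S + 2700L)))
        truth$type3 <- c(truth$type3, gid)
      } else {
        exons <- rbind(c(S, S + 800L), c(S + 1200L, S + 2000L))
        cds <- rbind(c(S + 200L, S + 800L), c(S + 1200L, S + 1700L))
        addTx(paste0(gid, ".t1"), gid, chr, strand, exons, cds)
        if (role == "type1") {
          # repeat covers the whole 1102 bp CDS footprint: fraction 1.0
          repeatRows[[length(repeatRows) + 1L]] <- data.frame(
            chr = chr, start = S + 200L, end = S + 1700L, class = "LTR/Gypsy")
          truth$type1 <- c(truth$type1, gid)
        } else if (role == "nearmiss") {
          # covers 882 of 1102 CDS bases: fraction 0.8004, below threshold
          repeatRows[[length(repeatRows) + 1L]] <- data.frame(
            chr = chr, start = S + 200L, end = S + 800L, class = "LTR/Copia")
          repeatRows[[length(repeatRows) + 1L]] <- data.frame(
            chr = chr, start = S + 1200L, end = S + 1480L, class = "LTR/Copia")
          truth$nearMiss <- c(truth$nearMiss, gid)
        } else if (role == "type2") {
          geneIdx <- geneIdx + 1L
          gid2 <- sprintf("gene%03d", geneIdx)
          addTx(paste0(gid2, ".t1"), gid2, chr, strand,
                exons = rbind(c(S + 1500L, S + 2400L)),
                cds = rbind(c(S + 1600L, S + 2300L)))
          truth$type2Removed <- c(truth$type2Removed, gid2)
          truth$type2Partner <- c(truth$type2Partner, gid)
          slotGenes[[i]] <- c(gid, gid2)
        }
      }
    }
    ids <- names(txList)
    # c() warns when per-chromosome GRanges share no seqlevels; benign here
    tx <- suppressWarnings(unname(do.call(c, unname(txList))))
    names(tx) <- ids
    ann <- newGeneAnnotation(tx,
      GenomicRanges::GRangesList(exonsList)[ids],
      GenomicRanges::GRangesList(cdsList)[ids],
      source = "simulated")

    # background repeats in the intergenic tail (never touching coding bases)
    for (cn in chrNames) {
      gapStart <- .SLOT_FIRST + perChr * .SLOT_PITCH + 200L
      repeatRows[[length(repeatRows) + 1L]] <- data.frame(
        chr = cn, start = gapStart, end = gapStart + 400L,
        class = "TIR/Mutator")
    }
    repDf <- do.call(rbind, repeatRows)
    repeats <- GenomicRanges::GRanges(repDf$chr,
                                      IRanges::IRanges(repDf$start, repDf$end))
    repeats$class_label <- repDf$class

    # evidence roles per slot, quotas realized exactly over genes
    nFull <- round(config$supportFull * nGenes)
    nAny <- round(config$supportAnyOnly * nGenes)
    quota <- c(full = nFull, any = nAny, none = nGenes - nFull - nAny)
    slotSize <- lengths(slotGenes)
    slotRole <- character(nSlots)
    for (i in order(-slotSize, sample.int(nSlots))) {
      s <- slotSize[i]
      ok <- names(quota)[quota >= s]
      if (length(ok) == 0L) {
        stop("infeasible support proportions for the planted gene layout")
      }
      pick <- ok[sample.int(length(ok), 1L)]
      slotRole[i] <- pick
      quota[pick] <- quota[pick] - s
    }
    fullIds <- unlist(slotGenes[slotRole == "full"], use.names = FALSE)
    anyIds <- unlist(slotGenes[slotRole == "any"], use.names = FALSE)
    noneIds <- unlist(slotGenes[slotRole == "none"], use.names = FALSE)

    g <- genes(ann)
    rnaRows <- list()
    protRows <- list()
    for (gid in fullIds) {
      i <- match(gid, names(g))
      rnaRows[[length(rnaRows) + 1L]] <- data.frame(
        chr = as.character(GenomicRanges::seqnames(g))[i],
        start = GenomicRanges::start(g)[i], end = GenomicRanges::end(g)[i])
      cds <- geneCdsFootprint(ann, gid)
      protRows[[length(protRows) + 1L]] <- data.frame(
        chr = as.character(GenomicRanges::seqnames(g))[i],
        start = min(GenomicRanges::start(cds)),
        end = max(GenomicRanges::end(cds)))
    }
    for (gid in anyIds) {
      i <- match(gid, names(g))
      st <- GenomicRanges::start(g)[i]
      rnaRows[[length(rnaRows) + 1L]] <- data.frame(
        chr = as.character(GenomicRanges::seqnames(g))[i],
        start = st, end = st + 50L)
      cds <- geneCdsFootprint(ann, gid)
      protRows[[length(protRows) + 1L]] <- data.frame(
        chr = as.character(GenomicRanges::seqnames(g))[i],
        start = min(GenomicRanges::start(cds)),
        end = min(GenomicRanges::start(cds)) + 20L)
    }
    toGr <- function(rows) {
      if (length(rows) == 0L) return(GenomicRanges::GRanges())
      df <- do.call(rbind, rows)
      GenomicRanges::reduce(GenomicRanges::GRanges(
        df$chr, IRanges::IRanges(df$start, df$end)), ignore.strand = TRUE)
    }
    rna <- toGr(rnaRows)
    protein <- toGr(protRows)
    truth$supportFull <- sort(fullIds)
    truth$supportAnyOnly <- sort(anyIds)
    truth$supportNone <- sort(noneIds)

    gids <- geneIds(ann)
    functionalIds <- sort(sample(gids,
                                 round(config$functionalFraction * nGenes)))
    orthogroupIds <- sort(sample(gids,
                                 round(config$orthogroupFraction * nGenes)))
    orthogroups <- simulateOrthogroupTables(config, genomeGenes = orthogroupIds)
    truth$functionalIds <- functionalIds
    truth$orthogroupIds <- orthogroupIds
    truth$telomereUnit <- canonicalUnit(config$telomereUnit)
    truth$telomereCopies <- config$telomereCopies

    files <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      files <- list(
        genome = file.path(outDir, "genome.fa"),
        gff3 = file.path(outDir, "annotation.gff3"),
        repeats = file.path(outDir, "repeats.bed"),
        rna = file.path(outDir, "rna.bed"),
        protein = file.path(outDir, "protein.bed"),
        truth = file.path(outDir, "truth.json"))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                  files$genome)
      writeGFF3(ann, files$gff3)
      writeBed(repeats, files$repeats)
      writeBed(rna, files$rna)
      writeBed(protein, files$protein)
      for (gname in names(orthogroups$tables)) {
        f <- file.path(outDir, paste0("orthogroups_", gname, ".tsv"))
        write.table(data.frame(gene = names(orthogroups$tables[[gname]]),
                               og = unname(orthogroups$tables[[gname]])),
                    f, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        files[[paste0("orthogroups_", gname)]] <- f
      }
      jsonlite::write_json(truth, files$truth, auto_unbox = TRUE)
    }
    list(genome = genome, annotation = ann, repeats = repeats, rna = rna,
         protein = protein, orthogroups = orthogroups$tables,
         orthogroupTruth = orthogroups$truth,
         functionalIds = functionalIds, orthogroupIds = orthogroupIds,
         truth = truth, files = files)
  })
}

#' Simulate multi-genome orthogroup assignment tables
#'
#' Builds assignment tables for several genomes with a controlled sharing
#' structure: a block of orthogroups present in every genome, a block per
#' consecutive genome pair, and a block unique to each genome. The first
#' genome's gene ids can be tied to a simulated annotation.
#'
#' @param config Output of [fixtureConfig()].
#' @param genomeGenes Optional gene ids of the first genome to which its
#'   orthogroups are assigned (recycled over its orthogroup list).
#' @return List with `tables` (named list of gene->orthogroup vectors) and
#'   `truth` (list: `shared`, `pair`, `unique` orthogroup id blocks and
#'   `labels`).
#' @export
simulateOrthogroupTables <- function(config = fixtureConfig(),
                                     genomeGenes = NULL) {
  nG <- config$nOrthoGenomes
  labels <- paste0("genome", seq_len(nG))
  shared <- sprintf("OG%04d", seq_len(config$nSharedOg))
  offset <- config$nSharedOg
  pair <- list()
  for (i in seq_len(max(nG - 1L, 0L))) {
    pair[[i]] <- sprintf("OG%04d", offset + seq_len(config$nPairOg))
    offset <- offset + config$nPairOg
  }
  uniq <- list()
  for (i in seq_len(nG)) {
    uniq[[i]] <- sprintf("OG%04d", offset + seq_len(config$nUniqueOg))
    offset <- offset + config$nUniqueOg
  }
  tables <- setNames(vector("list", nG), labels)
  for (i in seq_len(nG)) {
    ogs <- c(shared, if (i > 1L) pair[[i - 1L]], if (i < nG) pair[[i]],
             uniq[[i]])
    genes <- if (i == 1L && !is.null(genomeGenes) && length(genomeGenes)) {
      rep(genomeGenes, length.out = length(ogs))
    } else {
      sprintf("%s_g%04d", labels[i], seq_along(ogs))
    }
    # several genes may share an orthogroup, but each gene has exactly one
    ids <- make.unique(genes, sep = "_dup")
    tables[[i]] <- setNames(ogs, ids)
  }
  list(tables = tables,
       truth = list(shared = shared, pair = pair, unique = uniq,
                    labels = labels))
}

#' Simulate a two-parent cross and its phased child haplomes
#'
#' Parent B is derived from parent A by random substitutions at the
#' configured divergence rate (1.35% by default, an apple-like
#' heterozygosity); the child's two haplomes copy one parent each with a
#' small residual error rate emulating assembly error. No indels or
#' recombination are simulated. Truth records the parental origin of every
#' child chromosome.
#'
#' @param config Output of [fixtureConfig()].
#' @param outDir Optional directory for FASTA + truth output.
#' @return List with `parentA`, `parentB`, `childA`, `childB` (named
#'   character vectors of chromosome sequences), `truth` (data.frame:
#'   chromosome, origin) and `files`.
#' @export
simulateCross <- function(config = fixtureConfig(), outDir = NULL) {
  .withSeed(config$seed + 1L, {
    nChr <- config$crossChromosomes
    len <- config$crossLength
    chrN <- sprintf("chr%02d", seq_len(nChr))
    parentA <- setNames(vapply(chrN, function(x)
      .randomSeq(len, gc = config$gc), character(1)), chrN)
    parentB <- setNames(vapply(parentA, .mutateSeq,
                               rate = config$divergence,
                               FUN.VALUE = character(1)), chrN)
    childA <- setNames(vapply(parentA, .mutateSeq,
                              rate = config$childErrorRate,
                              FUN.VALUE = character(1)),
                       paste0("hapA_", chrN))
    childB <- setNames(vapply(parentB, .mutateSeq,
                              rate = config$childErrorRate,
                              FUN.VALUE = character(1)),
                       paste0("hapB_", chrN))
    truth <- data.frame(
      chromosome = c(names(childA), names(childB)),
      origin = rep(c("A", "B"), each = nChr))
    files <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      files <- list(parentA = file.path(outDir, "parentA.fa"),
                    parentB = file.path(outDir, "parentB.fa"),
                    child = file.path(outDir, "child_haplomes.fa"),
                    truth = file.path(outDir, "cross_truth.tsv"))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(parentA),
                                  files$parentA)
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(parentB),
                                  files$parentB)
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(childA, childB)),
                                  files$child)
      write.table(truth, files$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    list(parentA = parentA, parentB = parentB, childA = childA,
         childB = childB, truth = truth, files = files)
  })
}

#' Simulate a circular plastome with a planted inverted-repeat pair
#'
#' Assembles LSC + IRb + SSC + IRa (the IRa arm is the exact reverse
#' complement of IRb) from random sequence at the configured lengths, with
#' boundary bases fixed so the planted repeat is maximal (no chance
#' single-base extension across region boundaries), plus a feature table
#' with the configured category counts. Deterministic for a fixed seed.
#'
#' @param config Output of [fixtureConfig()].
#' @param outDir Optional directory for FASTA/TSV/JSON output.
#' @return List with `sequence` (character), `features` (`data.frame` with
#'   `gene` and `category` columns), `truth` (planted region lengths and
#'   coordinates) and `files`.
#' @export
simulatePlastome <- function(config = fixtureConfig(), outDir = NULL) {
  .withSeed(config$seed + 2L, {
    lsc <- config$plastomeLsc
    ssc <- config$plastomeSsc
    ir <- config$plastomeIr
    fix <- function(s, ch, pos) {
      substr(s, pos, pos) <- ch
      s
    }
    # an "A" at both flanks of each single-copy region blocks chance
    # extension of the planted repeat (A never complements A)
    lscSeq <- fix(fix(.randomSeq(lsc, gc = config$gc), "A", 1L), "A", lsc)
    sscSeq <- fix(fix(.randomSeq(ssc, gc = config$gc), "A", 1L), "A", ssc)
    irb <- .randomSeq(ir, gc = config$gc)
    sequence <- paste0(lscSeq, irb, sscSeq, .revcomp(irb))
    cat <- config$plastomeCategories
    features <- do.call(rbind, lapply(names(cat), function(cl) {
      prefix <- switch(cl, protein_coding = "pc", tRNA = "trn",
                       rRNA = "rrn", cl)
      data.frame(gene = sprintf("%s_%03d", prefix, seq_len(cat[[cl]])),
                 category = cl)
    }))
    truth <- list(lsc = lsc, ssc = ssc, ir = ir,
                  total = lsc + ssc + 2L * ir,
                  irb_start = lsc + 1L, irb_end = lsc + ir,
                  ira_start = lsc + ir + ssc + 1L,
                  ira_end = lsc + 2L * ir + ssc)
    files <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      files <- list(fasta = file.path(outDir, "plastome.fa"),
                    features = file.path(outDir, "plastome_features.tsv"),
                    truth = file.path(outDir, "plastome_truth.json"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(plastome = sequence)), files$fasta)
      write.table(features, files$features, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      jsonlite::write_json(truth, files$truth, auto_unbox = TRUE)
    }
    list(sequence = sequence, features = features, truth = truth,
         files = files)
  })
}
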