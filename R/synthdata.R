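.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.with_seed <- function(seed, expr) {
    if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. The seed is
#' mandatory: there is no implicit randomness anywhere in the generators.
#'
#' @param seed integer RNG seed.
#' @param nFamily family size.
#' @param divergence per-site substitution divergence: a single level, a
#'   range \code{c(min, max)} spread evenly over the members, or one level
#'   per member.
#' @param topology \code{"star"} (every member diverged independently from
#'   the root at its nominal level) or \code{"tree"} (members radiate from
#'   randomly chosen earlier members in \code{branchDivergence} steps, so
#'   nearest relatives stay close while root divergence spans the range).
#' @param branchDivergence per-branch divergence in tree mode.
#' @param readLen read length, nt.
#' @param coverage per-gene fold coverage.
#' @param errorRate per-base substitution error rate of simulated reads.
#' @param nBackground number of background reads.
#' @param decoyDivergence divergence of the paralog decoy family root from
#'   the marker root.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed, nFamily = 30L, divergence = c(0.2, 0.6),
                      topology = c("tree", "star"),
                      branchDivergence = 0.1, readLen = 150L,
                      coverage = 10, errorRate = 0.005,
                      nBackground = 10000L, decoyDivergence = 0.5) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    topology <- match.arg(topology)
    stopifnot(all(divergence >= 0 & divergence < 1),
              errorRate >= 0, errorRate < 1, decoyDivergence >= 0,
              decoyDivergence < 1, coverage > 0, readLen >= 1)
    structure(list(seed = as.integer(seed), nFamily = as.integer(nFamily),
                   divergence = divergence, topology = topology,
                   branchDivergence = branchDivergence,
                   readLen = as.integer(readLen), coverage = coverage,
                   errorRate = errorRate,
                   nBackground = as.integer(nBackground),
                   decoyDivergence = decoyDivergence),
              class = "SimConfig")
}

#' @rdname simConfig
#' @param config a \code{SimConfig}.
#' @param path JSON path.
#' @export
writeSimConfig <- function(config, path) {
    write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname simConfig
#' @export
readSimConfig <- function(path) {
    x <- read_json(path, simplifyVector = TRUE)
    do.call(simConfig, x)
}

#' The packaged synthetic root protein
#'
#' A 550-residue synthetic protein ("mcrA-like" in size and composition
#' only; generated, not copied from any database) used as the default root
#' for family simulations, so every example and test runs without any
#' download.
#'
#' @return a one-element [Biostrings::AAStringSet].
#' @export
rootProtein <- function() {
    readSequences(system.file("extdata", "mcra_like_root.faa",
                              package = "markerMiner"), alphabet = "aa")
}

#' Random protein sequence
#'
#' @param length residue count.
#' @param seed RNG seed (NULL inherits the current RNG state).
#' @return amino-acid string.
#' @export
randomProtein <- function(length, seed = NULL) {
    .with_seed(seed,
        paste(sample(.AA20, length, replace = TRUE), collapse = ""))
}

#' Mutate a protein by per-site substitution
#'
#' Each site is substituted independently with probability
#' \code{divergence}, drawing uniformly among the other 19 standard
#' residues.
#'
#' @param protein amino-acid string (or 1-element AAStringSet).
#' @param divergence per-site substitution probability.
#' @param seed RNG seed (NULL inherits the current RNG state).
#' @return mutated amino-acid string.
#' @export
mutateProtein <- function(protein, divergence, seed = NULL) {
    s <- strsplit(.chr1(protein), "")[[1]]
    .with_seed(seed, {
        hit <- which(runif(length(s)) < divergence)
        for (i in hit)
            s[i] <- sample(setdiff(.AA20, s[i]), 1L)
        paste(s, collapse = "")
    })
}

#' Simulate a divergent protein family
#'
#' Generates \code{n} family members from a root protein by per-site
#' substitution. In \code{"star"} topology each member is mutated
#' independently from the root at its nominal divergence level. In
#' \code{"tree"} topology members radiate from randomly chosen earlier
#' members in \code{branchDivergence} steps (nominal root divergence capped
#' at \code{max(divergence)}), which keeps nearest relatives close -- the
#' shape real families have.
#'
#' @param root root protein (string or 1-element AAStringSet); at least
#'   100 aa.
#' @param n number of members.
#' @param divergence as in [simConfig()].
#' @param seed mandatory RNG seed.
#' @param topology \code{"star"} or \code{"tree"}.
#' @param branchDivergence per-branch divergence for tree mode.
#' @return list: \code{members} (AAStringSet, names \code{fam_001}...),
#'   \code{rootDivergence} (nominal, per member), \code{pairwiseDivergence}
#'   (nominal additive matrix), \code{parents} (0 = root).
#' @export
simulateFamily <- function(root, n, divergence, seed,
                           topology = c("star", "tree"),
                           branchDivergence = 0.1) {
    topology <- match.arg(topology)
    rootc <- .chr1(root)
    if (nchar(rootc) < 100) stop("root protein must be >= 100 aa")
    levels <- if (length(divergence) == n) divergence
        else if (length(divergence) == 1L) rep(divergence, n)
        else if (length(divergence) == 2L)
            seq(divergence[1], divergence[2], length.out = n)
        else stop("divergence must have length 1, 2 or n")
    .with_seed(seed, {
        seqs <- character(n)
        parents <- integer(n)
        nomroot <- numeric(n)
        branch <- numeric(n)
        if (topology == "star") {
            for (i in seq_len(n)) {
                seqs[i] <- mutateProtein(rootc, levels[i])
                parents[i] <- 0L
                nomroot[i] <- levels[i]
                branch[i] <- levels[i]
            }
        } else {
            dmax <- max(levels)
            for (i in seq_len(n)) {
                if (i == 1L) {
                    parents[i] <- 0L
                    branch[i] <- min(levels)
                } else {
                    elig <- c(0L, which(nomroot[seq_len(i - 1L)] +
                                            branchDivergence <= dmax))
                    parents[i] <- elig[sample.int(length(elig), 1L)]
                    branch[i] <- branchDivergence
                }
                pseq <- if (parents[i] == 0L) rootc else seqs[parents[i]]
                pnom <- if (parents[i] == 0L) 0 else nomroot[parents[i]]
                seqs[i] <- mutateProtein(pseq, branch[i])
                nomroot[i] <- pnom + branch[i]
            }
        }
        members <- AAStringSet(seqs)
        names(members) <- sprintf("fam_%03d", seq_len(n))
        pw <- .tree_pairwise(parents, branch)
        dimnames(pw) <- list(names(members), names(members))
        list(members = members, rootDivergence = nomroot,
             pairwiseDivergence = pw, parents = parents)
    })
}

# Additive nominal pairwise divergence along the simulated tree.
.tree_pairwise <- function(parents, branch) {
    n <- length(parents)
    path <- function(i) {  # branch-length map from node i up to root
        d <- numeric(0); names(d) <- character(0)
        while (i != 0L) {
            d[as.character(i)] <- branch[i]
            i <- parents[i]
        }
        d
    }
    paths <- lapply(seq_len(n), path)
    pw <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i >= j) next
        anc_i <- names(paths[[i]]); anc_j <- names(paths[[j]])
        shared <- intersect(anc_i, anc_j)
        d <- sum(paths[[i]][setdiff(anc_i, shared)]) +
            sum(paths[[j]][setdiff(anc_j, shared)])
        pw[i, j] <- pw[j, i] <- d
    }
    pw
}

#' Reverse-translate a protein with uniform synonymous codons
#'
#' Each residue gets a codon drawn uniformly from its synonymous set in the
#' genetic-code table; \code{O} (pyrrolysine readthrough) maps to TAG.
#' Translating the result in frame +1 reproduces the protein exactly.
#'
#' @param protein amino-acid string or 1-element AAStringSet (no stops, no
#'   X).
#' @param seed RNG seed (NULL inherits the current RNG state).
#' @param code genetic-code table id.
#' @return nucleotide string.
#' @export
reverseTranslate <- function(protein, seed = NULL, code = "11") {
    p <- strsplit(.chr1(protein), "")[[1]]
    tab <- .codonTable(code)
    bases <- c("A", "C", "G", "T")
    codons <- character(64)
    k <- 1L
    for (a in bases) for (b in bases) for (c in bases) {
        codons[k] <- paste0(a, b, c); k <- k + 1L
    }
    aa <- strsplit(tab, "")[[1]]
    syn <- split(codons, aa)
    syn[["O"]] <- "TAG"
    if (any(!p %in% names(syn)) || any(p %in% c("*", "X")))
        stop("protein contains residues without a defined codon set")
    .with_seed(seed, {
        picked <- vapply(p, function(r) {
            cs <- syn[[r]]
            cs[sample.int(length(cs), 1L)]
        }, character(1), USE.NAMES = FALSE)
        paste(picked, collapse = "")
    })
}

#' Simulate reads from genes, with a complete truth table
#'
#' Read count per gene is \code{round(coverage * geneLen / readLen)} unless
#' \code{nReads} fixes the total (distributed over genes proportionally to
#' length, largest remainder). Start positions and strand are uniform;
#' substitution errors are i.i.d. per base. Genes shorter than the read
#' length yield whole-gene reads flagged \code{short}.
#'
#' @param genes named [Biostrings::DNAStringSet].
#' @param coverage per-gene fold coverage.
#' @param readLen read length, nt.
#' @param errorRate per-base substitution probability.
#' @param seed mandatory RNG seed.
#' @param origin truth label for these reads: \code{"target"},
#'   \code{"decoy"} or \code{"background"}.
#' @param divergence optional named per-gene nominal divergence recorded in
#'   the truth table.
#' @param nReads optional exact total read count overriding
#'   \code{coverage}.
#' @param idPrefix prefix for read ids.
#' @return list: \code{reads} (DNAStringSet), \code{truth} (data.frame:
#'   read_id, origin, family_member_id, start, end, strand,
#'   nominal_divergence, short).
#' @export
simulateReads <- function(genes, coverage = 10, readLen = 150L,
                          errorRate = 0, seed, origin = "target",
                          divergence = NULL, nReads = NULL,
                          idPrefix = origin) {
    stopifnot(coverage > 0, errorRate >= 0, errorRate < 1)
    lens <- width(genes)
    if (is.null(nReads)) {
        counts <- round(coverage * lens / readLen)
    } else {
        frac <- nReads * lens / sum(lens)
        counts <- floor(frac)
        rem <- nReads - sum(counts)
        if (rem > 0) {
            extra <- order(frac - counts, decreasing = TRUE)[seq_len(rem)]
            counts[extra] <- counts[extra] + 1L
        }
    }
    .with_seed(seed, {
        reads <- character(0); rows <- list(); k <- 0L
        for (g in seq_along(genes)) {
            gs <- as.character(genes[[g]])
            L <- lens[g]
            short <- L < readLen
            for (r in seq_len(counts[g])) {
                k <- k + 1L
                if (short) {
                    s0 <- 0L; rl <- L
                } else {
                    s0 <- sample.int(L - readLen + 1L, 1L) - 1L
                    rl <- readLen
                }
                frag <- substr(gs, s0 + 1L, s0 + rl)
                strand <- sample(c("+", "-"), 1L)
                if (errorRate > 0) {
                    ch <- strsplit(frag, "")[[1]]
                    hit <- which(runif(rl) < errorRate)
                    for (i in hit)
                        ch[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                                ch[i]), 1L)
                    frag <- paste(ch, collapse = "")
                }
                if (strand == "-") frag <- .revcomp_chr(frag)
                reads[k] <- frag
                rows[[k]] <- data.frame(
                    read_id = sprintf("%s_%05d", idPrefix, k),
                    origin = origin,
                    family_member_id = names(genes)[g],
                    start = s0, end = s0 + rl, strand = strand,
                    nominal_divergence =
                        if (is.null(divergence)) NA_real_
                        else unname(divergence[names(genes)[g]]),
                    short = short, stringsAsFactors = FALSE)
            }
        }
        truth <- do.call(rbind, rows)
        out <- DNAStringSet(reads)
        names(out) <- truth$read_id
        list(reads = out, truth = truth)
    })
}

#' Score a retained-read set against the simulation truth
#'
#' @param retainedIds character vector of retained read ids.
#' @param truth truth table covering all simulated reads (rbind of
#'   [simulateReads()] truth tables).
#' @return list: \code{precision} (retained target / retained; NA when
#'   nothing is retained), \code{recall} (retained target / all target),
#'   \code{perOrigin} (data.frame of total and retained counts per origin
#'   class).
#' @export
evaluateAgainstTruth <- function(retainedIds, truth) {
    unknown <- setdiff(retainedIds, truth$read_id)
    if (length(unknown) > 0)
        stop("read id(s) not in truth table: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    ret <- truth$read_id %in% retainedIds
    tgt <- truth$origin == "target"
    per <- aggregate(cbind(total = rep(1L, nrow(truth)), retained = ret),
                     by = list(origin = truth$origin), FUN = sum)
    list(precision = if (any(ret)) sum(ret & tgt) / sum(ret) else NA_real_,
         recall = if (any(tgt)) sum(ret & tgt) / sum(tgt) else NA_real_,
         perOrigin = per)
}

#' Build the standing curation benchmark
#'
#' Constructs a tree-simulated marker family and splits it into a seed
#' database (the lowest-root-divergence core, the role a curated seed
#' family plays) and a candidate radiation reaching
#' \code{max(divergence)} from the root, plus unrelated random decoy
#' proteins long enough to pass the full-length gate. Used to measure how
#' well self-hit BSR curation separates true family members from noise.
#'
#' @param seed integer seed.
#' @param nSeed seed-core size.
#' @param nCandidates family candidates beyond the core.
#' @param nDecoys unrelated decoy count.
#' @param decoyLen decoy protein length (default 500, above the default
#'   0.8 x median-seed-length gate for a 550-residue family).
#' @param divergence family root-divergence envelope.
#' @return list: \code{seedDb}, \code{candidates} (family members),
#'   \code{decoys}, \code{family} (the full [simulateFamily()] output).
#' @export
curationBenchmark <- function(seed, nSeed = 10L, nCandidates = 30L,
                              nDecoys = 100L, decoyLen = 500L,
                              divergence = c(0.1, 0.6)) {
    root <- rootProtein()
    withr::with_seed(seed, {
        fam <- simulateFamily(root, nSeed + nCandidates, divergence,
                              seed = NULL, topology = "tree")
        ord <- order(fam$rootDivergence, seq_along(fam$rootDivergence))
        seed_idx <- sort(ord[seq_len(nSeed)])
        cand_idx <- sort(setdiff(seq_along(fam$rootDivergence), seed_idx))
        decoys <- AAStringSet(vapply(seq_len(nDecoys), function(i)
            randomProtein(decoyLen), character(1)))
        names(decoys) <- sprintf("decoy_%03d", seq_len(nDecoys))
        list(seedDb = fam$members[seed_idx],
             candidates = fam$members[cand_idx],
             decoys = decoys, family = fam)
    })
}

#' Build the standing spike-in benchmark
#'
#' Constructs, under one seed, the full truth-labelled screening benchmark:
#' a tree-simulated marker family with its greedily clustered reference
#' database; a paralog decoy family diverged \code{decoyDivergence} from
#' the marker root; a pool of unrelated background genes; reads from all
#' three origins; and an outgroup database holding the decoy and background
#' proteins (the role an all-known-proteins collection plays for real
#' screens: the true source of any spurious marker hit is present, so its
#' BSR drops).
#'
#' @param seed integer seed driving every random choice.
#' @param nTargetReads,nDecoyReads,nBackgroundReads read counts per origin.
#' @param config a [simConfig()]; its seed is overridden by \code{seed}.
#' @param nBackgroundGenes,backgroundProteinLen background gene pool shape.
#' @param nDecoy decoy family size.
#' @return list: \code{markerDb} ([ReferenceDb-class]), \code{outgroupDb}
#'   (AAStringSet), \code{reads} (DNAStringSet, interleaved), \code{truth},
#'   \code{family}, \code{decoys}, \code{background}, \code{config}.
#' @export
spikeInBenchmark <- function(seed, nTargetReads = 200L,
                             nDecoyReads = 200L,
                             nBackgroundReads = 10000L,
                             config = simConfig(seed),
                             nBackgroundGenes = 40L,
                             backgroundProteinLen = 400L,
                             nDecoy = 10L) {
    root <- rootProtein()
    withr::with_seed(seed, {
        fam <- simulateFamily(root, config$nFamily, config$divergence,
                              seed = NULL, topology = config$topology,
                              branchDivergence = config$branchDivergence)
        markerDb <- clusterGreedy(fam$members, 0.90)
        decoyRoot <- mutateProtein(root, config$decoyDivergence)
        dec <- simulateFamily(decoyRoot, nDecoy, 0.1, seed = NULL,
                              topology = "star")
        names(dec$members) <- sprintf("decoy_%03d", seq_len(nDecoy))
        bg <- AAStringSet(vapply(seq_len(nBackgroundGenes), function(i)
            randomProtein(backgroundProteinLen), character(1)))
        names(bg) <- sprintf("bg_%03d", seq_len(nBackgroundGenes))
        rt <- function(x) DNAStringSet(vapply(as.character(x),
            function(p) reverseTranslate(p), character(1),
            USE.NAMES = FALSE))
        famGenes <- rt(fam$members); names(famGenes) <- names(fam$members)
        decGenes <- rt(dec$members); names(decGenes) <- names(dec$members)
        bgGenes <- rt(bg); names(bgGenes) <- names(bg)
        tg <- simulateReads(famGenes, readLen = config$readLen,
                            errorRate = config$errorRate, seed = NULL,
                            origin = "target", nReads = nTargetReads)
        dg <- simulateReads(decGenes, readLen = config$readLen,
                            errorRate = config$errorRate, seed = NULL,
                            origin = "decoy", nReads = nDecoyReads)
        bgr <- simulateReads(bgGenes, readLen = config$readLen,
                             errorRate = config$errorRate, seed = NULL,
                             origin = "background",
                             nReads = nBackgroundReads)
        reads <- c(tg$reads, dg$reads, bgr$reads)
        truth <- rbind(tg$truth, dg$truth, bgr$truth)
        perm <- sample.int(length(reads))
        list(markerDb = markerDb,
             outgroupDb = c(dec$members, bg),
             reads = reads[perm], truth = truth[perm, , drop = FALSE],
             family = fam, decoys = dec, background = bg,
             genes = list(family = famGenes, decoy = decGenes,
                          background = bgGenes),
             config = config)
    })
}
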