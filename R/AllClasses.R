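#' Scoring scheme for pairwise alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw scores into bit scores.
#' A gap of length L costs \code{gapOpen + (L - 1) * gapExtend}: the opening
#' charge is levied on the first gap residue.
#'
#' @slot name scheme label, e.g. \code{"BLOSUM62"}.
#' @slot matrix symmetric integer substitution matrix whose dimnames are
#'   single residues.
#' @slot alphabet residue alphabet, in matrix order, collapsed to one string.
#' @slot gapOpen positive integer gap opening penalty (cost of a length-1
#'   gap).
#' @slot gapExtend positive integer per-residue gap extension penalty.
#' @slot lambda,K Karlin-Altschul parameters; bit score =
#'   (lambda * raw - ln K) / ln 2.
#' @slot type \code{"aa"} or \code{"dna"}.
#'
#' @seealso [scoringScheme()], [dnaScoringScheme()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
    representation(name = "character", matrix = "matrix",
                   alphabet = "character", gapOpen = "integer",
                   gapExtend = "integer", lambda = "numeric", K = "numeric",
                   type = "character"))

setValidity("ScoringScheme", function(object) {
    m <- object@matrix
    if (!is.numeric(m) || nrow(m) != ncol(m))
        return("matrix must be square and numeric")
    if (!isTRUE(all.equal(m, t(m))))
        return("substitution matrix must be symmetric")
    if (nchar(object@alphabet) != nrow(m))
        return("alphabet length must match matrix dimension")
    if (object@gapOpen < 1L || object@gapExtend < 1L)
        return("gap penalties must be positive")
    if (object@gapExtend > object@gapOpen)
        return("gapExtend must not exceed gapOpen")
    if (object@lambda <= 0 || object@K <= 0)
        return("lambda and K must be positive")
    TRUE
})

#' Scored local (or global) pairwise alignment
#'
#' @slot rawScore integer alignment score under the scheme's matrix and
#'   affine gap penalties; 0 for an empty local alignment.
#' @slot bitScore normalized score, (lambda * raw - ln K) / ln 2.
#' @slot identityFraction identical residue pairs / columns (0 when empty).
#' @slot identities,columns integer counts; columns include gap columns.
#' @slot queryInterval,targetInterval 0-based half-open coordinates of the
#'   aligned region.
#' @slot frame translated-search frame in \{+1,+2,+3,-1,-2,-3\}, or 0 for
#'   protein-vs-protein.
#' @slot alignedQuery,alignedTarget gapped alignment strings.
#' @exportClass LocalAlignment
setClass("LocalAlignment",
    representation(rawScore = "integer", bitScore = "numeric",
                   identityFraction = "numeric", identities = "integer",
                   columns = "integer", queryInterval = "integer",
                   targetInterval = "integer", frame = "integer",
                   alignedQuery = "character", alignedTarget = "character"))

#' Non-redundant centroid reference database
#'
#' Produced by [clusterGreedy()]: sequences are visited in length-descending
#' order and each joins the first centroid it matches at or above the
#' identity threshold, else founds a new centroid.
#'
#' @slot centroids [Biostrings::AAStringSet] of cluster representatives, in
#'   founding order.
#' @slot membership data.frame with columns \code{member_id},
#'   \code{centroid_id}, \code{identity}.
#' @slot identityThreshold global-alignment identity threshold used.
#' @slot provenance list of construction metadata.
#' @exportClass ReferenceDb
setClass("ReferenceDb",
    representation(centroids = "AAStringSet", membership = "data.frame",
                   identityThreshold = "numeric", provenance = "list"))

setValidity("ReferenceDb", function(object) {
    if (anyDuplicated(names(object@centroids)))
        return("duplicated centroid ids")
    need <- c("member_id", "centroid_id", "identity")
    if (!all(need %in% colnames(object@membership)))
        return("membership must have member_id, centroid_id, identity")
    if (!all(object@membership$centroid_id %in% names(object@centroids)))
        return("membership refers to unknown centroids")
    if (object@identityThreshold <= 0 || object@identityThreshold > 1)
        return("identityThreshold must be in (0, 1]")
    TRUE
})

#' Result of screening one read set against a marker database
#'
#' @slot datasetId dataset label (SRA/MG-RAST style).
#' @slot hits best-hit table from [screenReads()].
#' @slot retained [Biostrings::DNAStringSet] of reads surviving the
#'   outgroup-BSR filter.
#' @slot bsr outgroup BsrRecord table.
#' @slot counts named integer vector: screened, hit, retained.
#' @slot gatePassed TRUE when the retained count strictly exceeds the
#'   dataset gate.
#' @slot approxCoverage retained * readLen / geneLen.
#' @exportClass MinedReadSet
setClass("MinedReadSet",
    representation(datasetId = "character", hits = "data.frame",
                   retained = "DNAStringSet", bsr = "data.frame",
                   counts = "integer", gatePassed = "logical",
                   approxCoverage = "numeric"))

setValidity("MinedReadSet", function(object) {
    cn <- object@counts
    if (!all(c("screened", "hit", "retained") %in% names(cn)))
        return("counts must name screened, hit, retained")
    if (cn["retained"] > cn["hit"] || cn["hit"] > cn["screened"])
        return("counts must satisfy retained <= hit <= screened")
    TRUE
})

#' Reconstructed gene contig
#'
#' @slot contigId contig label.
#' @slot datasetId source dataset label (NA when unknown).
#' @slot consensus [Biostrings::DNAString] per-column majority consensus.
#' @slot depth integer per-position read coverage, same length as the
#'   consensus.
#' @slot members data.frame of read placements: \code{read_id},
#'   \code{start}, \code{end} (0-based half-open on the consensus),
#'   \code{strand}, \code{placed_rank}.
#' @exportClass GeneContig
setClass("GeneContig",
    representation(contigId = "character", datasetId = "character",
                   consensus = "DNAString", depth = "integer",
                   members = "data.frame"))

setValidity("GeneContig", function(object) {
    if (length(object@depth) != length(object@consensus))
        return("depth must have one entry per consensus position")
    TRUE
})

#' Recruitment profile at an identity floor
#'
#' @slot counts named integer: per-centroid counts of queries whose best hit
#'   reaches the identity floor.
#' @slot histogram data.frame (bin_low, bin_high, count) of best-hit
#'   identities, bin width 0.01 on [0, 1].
#' @slot belowFloorCount,belowFloorFraction queries with a hit whose best
#'   identity falls below the floor (fraction of queries with any hit).
#' @slot identityFloor the floor (default 0.90).
#' @slot boundary \code{">="}: identity equal to the floor counts as
#'   recruited, so recruited and below-floor sets are complementary.
#' @slot nQueries,nWithHit totals.
#' @exportClass RecruitmentProfile
setClass("RecruitmentProfile",
    representation(counts = "integer", histogram = "data.frame",
                   belowFloorCount = "integer", belowFloorFraction = "numeric",
                   identityFloor = "numeric", boundary = "character",
                   nQueries = "integer", nWithHit = "integer"))

setValidity("RecruitmentProfile", function(object) {
    if (sum(object@histogram$count) != object@nWithHit)
        return("histogram total must equal the number of queries with a hit")
    if (sum(object@counts) + object@belowFloorCount != object@nWithHit)
        return("recruited + below-floor must equal queries with a hit")
    TRUE
})

#' Chemical species with elemental composition
#'
#' @slot name species label.
#' @slot formula named numeric vector of element counts.
#' @slot charge integer formal charge.
#' @slot dGf0 standard free energy of formation, kJ/mol (NA when unknown).
#' @exportClass Species
setClass("Species",
    representation(name = "character", formula = "numeric",
                   charge = "integer", dGf0 = "numeric"))

setValidity("Species", function(object) {
    f <- object@formula
    if (length(f) == 0 || is.null(names(f)) || any(names(f) == ""))
        return("formula must be a named element -> count vector")
    if (any(f < 0)) return("element counts must be non-negative")
    TRUE
})

#' Chemical reaction with stoichiometric coefficients
#'
#' @slot name reaction label.
#' @slot reactants,products lists of \code{list(species = Species,
#'   coef = positive number)}.
#' @slot dgTotal whole-reaction standard free-energy change, kJ/mol
#'   (negative = exergonic; NA when not supplied).
#' @exportClass Reaction
setClass("Reaction",
    representation(name = "character", reactants = "list",
                   products = "list", dgTotal = "numeric"))

setValidity("Reaction", function(object) {
    chk <- function(side) {
        for (x in side) {
            if (!is(x$species, "Species")) return("each term needs a Species")
            if (is.null(x$coef) || x$coef <= 0)
                return("stoichiometric coefficients must be positive")
        }
        TRUE
    }
    r <- chk(object@reactants); if (!isTRUE(r)) return(r)
    chk(object@products)
})
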