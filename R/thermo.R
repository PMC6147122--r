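#' Parse a molecular formula
#'
#' Accepts simple Hill-style formulas like \code{"CH3OH"} or \code{"CO2"}
#' (element symbols with optional counts; no parentheses).
#'
#' @param x formula string, or an already-named numeric element-count
#'   vector (returned unchanged).
#' @return named numeric vector of element counts.
#' @examples
#' parseFormula("CH3OH")  # C 1, H 4, O 1
#' @export
parseFormula <- function(x) {
    if (is.numeric(x)) return(x)
    m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    if (length(toks) == 0 || sum(attr(m, "match.length")) != nchar(x))
        stop("cannot parse formula: ", x)
    el <- sub("[0-9]*$", "", toks)
    ct <- as.numeric(sub("^[A-Za-z]+", "", toks))
    ct[is.na(ct)] <- 1
    vapply(split(ct, factor(el, levels = unique(el))), sum, numeric(1))
}

#' Construct a chemical species
#'
#' @param name species label.
#' @param formula formula string or named element-count vector.
#' @param charge integer formal charge.
#' @param dGf0 standard free energy of formation, kJ/mol (NA when
#'   unknown).
#' @return a [Species-class].
#' @examples
#' species("methanol", "CH3OH")
#' species("formate", "CHO2", charge = -1)
#' @export
species <- function(name, formula, charge = 0L, dGf0 = NA_real_) {
    f <- parseFormula(formula)
    fv <- as.numeric(f)
    names(fv) <- names(f)
    new("Species", name = name, formula = fv,
        charge = as.integer(charge), dGf0 = as.numeric(dGf0))
}

setMethod("show", "Species", function(object) {
    cat(sprintf("Species %s: %s charge %+d dGf0 %s kJ/mol\n", object@name,
                paste0(names(object@formula), object@formula,
                       collapse = " "),
                object@charge,
                ifelse(is.na(object@dGf0), "NA",
                       format(object@dGf0))))
})

#' Construct a reaction
#'
#' @param name reaction label.
#' @param reactants,products named numeric vectors of stoichiometric
#'   coefficients whose names index \code{speciesList}, or lists of
#'   \code{list(species = , coef = )}.
#' @param speciesList named list of [Species-class] used to resolve
#'   coefficient names.
#' @param dgTotal whole-reaction standard free-energy change, kJ/mol
#'   (negative = exergonic).
#' @return a [Reaction-class].
#' @export
reaction <- function(name, reactants, products, speciesList = NULL,
                     dgTotal = NA_real_) {
    side <- function(x) {
        if (is.numeric(x)) {
            stopifnot(!is.null(names(x)), !is.null(speciesList))
            lapply(seq_along(x), function(i) {
                sp <- speciesList[[names(x)[i]]]
                if (is.null(sp)) stop("unknown species: ", names(x)[i])
                list(species = sp, coef = unname(x[i]))
            })
        } else x
    }
    new("Reaction", name = name, reactants = side(reactants),
        products = side(products), dgTotal = as.numeric(dgTotal))
}

setMethod("show", "Reaction", function(object) {
    fmt <- function(side) paste(vapply(side, function(x)
        paste0(ifelse(x$coef == 1, "", paste0(x$coef, " ")),
               x$species@name), character(1)), collapse = " + ")
    cat(sprintf("Reaction %s: %s -> %s%s\n", object@name,
                fmt(object@reactants), fmt(object@products),
                if (is.na(object@dgTotal)) "" else
                    sprintf("  (dG0' = %g kJ/mol)", object@dgTotal)))
})

#' Element and charge balance residuals of a reaction
#'
#' Residual = products minus reactants, per element and for charge; the
#' reaction is balanced exactly when every residual is zero.
#'
#' @param rxn a [Reaction-class].
#' @return named numeric residual vector (elements, then \code{charge}).
#' @export
balanceCheck <- function(rxn) {
    acc <- function(side, sign) {
        out <- numeric(0); ch <- 0
        for (x in side) {
            f <- x$species@formula * x$coef
            for (e in names(f)) {
                cur <- if (e %in% names(out)) out[[e]] else 0
                out[e] <- cur + sign * f[[e]]
            }
            ch <- ch + sign * x$species@charge * x$coef
        }
        list(el = out, charge = ch)
    }
    p <- acc(rxn@products, 1); r <- acc(rxn@reactants, -1)
    els <- union(names(p$el), names(r$el))
    res <- vapply(els, function(e) {
        a <- p$el[e]; b <- r$el[e]
        (if (is.na(a)) 0 else a) + (if (is.na(b)) 0 else b)
    }, numeric(1))
    c(res, charge = p$charge + r$charge)
}

#' Whether a reaction is balanced
#'
#' @inheritParams balanceCheck
#' @param tol numeric tolerance on the residuals.
#' @export
isBalanced <- function(rxn, tol = 1e-9) {
    all(abs(balanceCheck(rxn)) <= tol)
}

#' Reaction standard free-energy change from formation energies
#'
#' \eqn{\Delta G = \sum \nu \Delta G_f^0(products) - \sum \nu \Delta
#' G_f^0(reactants)}, kJ/mol reaction.
#'
#' @inheritParams balanceCheck
#' @return kJ/mol (negative = exergonic).
#' @export
reactionDg <- function(rxn) {
    term <- function(side, sign) {
        s <- 0
        for (x in side) {
            if (is.na(x$species@dGf0))
                stop("missing dGf0 for species: ", x$species@name)
            s <- s + sign * x$coef * x$species@dGf0
        }
        s
    }
    term(rxn@products, 1) + term(rxn@reactants, -1)
}

#' Free energy per mole of substrate
#'
#' @param dgTotal whole-reaction free-energy change, kJ/mol reaction.
#' @param substrateCoefficient stoichiometric coefficient of the substrate
#'   (a positive integer).
#' @return kJ/mol substrate.
#' @examples
#' perSubstrate(-203.4, 3)   # -67.8 kJ/mol methanol
#' perSubstrate(-319.4, 4)   # -79.85 kJ/mol methanol
#' @export
perSubstrate <- function(dgTotal, substrateCoefficient) {
    if (substrateCoefficient < 1)
        stop("substrate coefficient must be a positive integer")
    dgTotal / substrateCoefficient
}

#' Read reactions from JSON
#'
#' The JSON layout is a list of objects with fields \code{name},
#' \code{dG_total} (optional), \code{substrate} (optional name),
#' \code{reactants} and \code{products}, each side a list of
#' \code{\{species, formula, charge, dGf0, coef\}} objects.
#'
#' @param path JSON file.
#' @return named list of [Reaction-class]; each carries attributes
#'   \code{substrate} and \code{substrate_coef} when declared.
#' @export
readReactions <- function(path) {
    raw <- read_json(path, simplifyVector = FALSE)
    out <- lapply(raw, function(rx) {
        side <- function(terms) lapply(terms, function(t)
            list(species = species(t$species, t$formula,
                                   charge = t$charge %||% 0L,
                                   dGf0 = t$dGf0 %||% NA_real_),
                 coef = t$coef %||% 1))
        r <- reaction(rx$name, side(rx$reactants), side(rx$products),
                      dgTotal = rx$dG_total %||% NA_real_)
        if (!is.null(rx$substrate)) {
            attr(r, "substrate") <- rx$substrate
            co <- vapply(r@reactants, function(x)
                if (x$species@name == rx$substrate) x$coef else 0,
                numeric(1))
            attr(r, "substrate_coef") <- max(co)
        }
        r
    })
    names(out) <- vapply(raw, `[[`, character(1), "name")
    out
}

#' Free-energy report for a set of reactions
#'
#' One row per reaction: whole-reaction free energy (supplied
#' \code{dgTotal}, else computed from formation energies), per-substrate
#' value, and a balance flag.
#'
#' @param rxns named list of [Reaction-class] (as from [readReactions()]).
#' @param path optional TSV output path.
#' @return data.frame: reaction, dg_total, substrate, per_substrate,
#'   balanced.
#' @export
thermoReport <- function(rxns, path = NULL) {
    rows <- lapply(rxns, function(r) {
        dg <- if (!is.na(r@dgTotal)) r@dgTotal else reactionDg(r)
        sub <- attr(r, "substrate") %||% NA_character_
        co <- attr(r, "substrate_coef") %||% NA_real_
        data.frame(reaction = r@name, dg_total = dg, substrate = sub,
                   per_substrate = if (is.na(co)) NA_real_
                       else perSubstrate(dg, co),
                   balanced = isBalanced(r), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!is.null(path))
        write.table(out, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    out
}
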