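## The combined-state model.
##
## Each line x marker is assigned the joint label Pd.Pn.dose combining
## the maternal haplotype (D1/D2), the paternal haplotype (N1/N2) and
## the paternal copy number (0/1/2).  A deleted paternal segment has no
## haplotype, and an insertion is a duplication of the transmitted
## paternal copy (it keeps that copy's single haplotype label), so the
## universe closes at exactly 10 states: {D1,D2} x ({NA}x{0} u
## {N1,N2}x{1,2}).  With every state present, pairwise testing of all
## unordered state pairs yields choose(10,2) = 45 comparisons.

#' The canonical 10-state universe
#'
#' @return character vector of the 10 state labels in canonical order.
#' @export
enumerateStates <- function() {
  out <- character(0)
  for (pd in c("D1", "D2")) {
    out <- c(out, paste(pd, "NA", 0, sep = "."))
    for (pn in c("N1", "N2"))
      for (dose in 1:2)
        out <- c(out, paste(pd, pn, dose, sep = "."))
  }
  out
}

#' The six QTL classification groups
#'
#' @return character vector of the group labels.
#' @export
qtlGroups <- function() {
  c("deletion", "deletion+insertion", "insertion",
    "P. deltoides", "P. deltoides + P. nigra", "P. nigra")
}

#' Assign combined states to every line x marker
#'
#' A cell is missing when the Pd haplotype is NA, the dose is NA, or
#' the Pn haplotype is NA at non-zero dose.
#'
#' @param cm a [CommonMarkers-class] object.
#' @return character matrix (markers x lines) of state labels or NA;
#'   every non-missing label belongs to [enumerateStates()].
#' @export
assignStates <- function(cm) {
  pd <- cm@pd; pn <- cm@pn; dose <- cm@dose
  bad <- !is.na(dose) & dose == 0L & !is.na(pn)
  stopifNot1(!any(bad), "dose 0 with non-NA Pn haplotype violates %s",
             "the state invariant")
  st <- matrix(NA_character_, nrow(pd), ncol(pd), dimnames = dimnames(pd))
  ok0 <- !is.na(pd) & !is.na(dose) & dose == 0L
  st[ok0] <- paste(pd[ok0], "NA", 0, sep = ".")
  okN <- !is.na(pd) & !is.na(dose) & dose > 0L & !is.na(pn)
  st[okN] <- paste(pd[okN], pn[okN], dose[okN], sep = ".")
  st
}

#' Pairwise two-group permutation tests among states at one marker
#'
#' For every unordered pair of states with at least `minGroup` observed
#' lines each, a Monte-Carlo permutation test of the absolute mean
#' difference: group labels are reshuffled within the pair's lines and
#' `p_raw = (1 + #{permuted |diff| >= observed}) / (1 + nPerm)`
#' (add-one estimator; two identical groups give p = 1).
#'
#' @param y numeric trait values.
#' @param states state labels aligned to `y` (NA = unassigned).
#' @param nPerm permutations per pair.
#' @param minGroup minimum lines per state.
#' @param seed optional integer seed.
#' @return data.frame (state1, state2, n1, n2, diff, p_raw), one row
#'   per qualifying pair (state1 < state2); zero rows when fewer than
#'   two states qualify.
#' @export
pairwiseStateTests <- function(y, states, nPerm = 1000, minGroup = 5,
                               seed = NULL) {
  ok <- !is.na(y) & !is.na(states)
  y <- y[ok]; states <- states[ok]
  tab <- table(states)
  qual <- sort(names(tab)[tab >= minGroup])
  empty <- data.frame(state1 = character(), state2 = character(),
                      n1 = integer(), n2 = integer(), diff = numeric(),
                      p_raw = numeric(), stringsAsFactors = FALSE)
  if (length(qual) < 2) return(empty)
  prs <- utils::combn(qual, 2)
  withSeed(seed, {
    res <- lapply(seq_len(ncol(prs)), function(k) {
      s1 <- prs[1, k]; s2 <- prs[2, k]
      v1 <- y[states == s1]; v2 <- y[states == s2]
      n1 <- length(v1); n2 <- length(v2)
      obs <- abs(mean(v1) - mean(v2))
      exceed <- .pairPermCount(c(v1, v2), n1, nPerm, obs)
      data.frame(state1 = s1, state2 = s2, n1 = n1, n2 = n2,
                 diff = mean(v1) - mean(v2),
                 p_raw = (1 + exceed) / (1 + nPerm),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (validated, then
#' delegated to the standard step-up implementation).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  stopifNot1(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

## Type one significant state pair as mechanism evidence.
##   "del" / "ins"    dosage contrast on a shared haplotype background
##   "Pd" / "Pn"      single-haplotype contrast at equal dose
##   "PdPn"           both haplotypes differ at equal dose
##   NA               confounded (dose and haplotype both differ, or the
##                    0-vs-2 contrast, which mixes a deletion and an
##                    insertion difference with no regular-dose anchor)
classifyPair <- function(s1, s2) {
  p1 <- strsplit(s1, ".", fixed = TRUE)[[1]]
  p2 <- strsplit(s2, ".", fixed = TRUE)[[1]]
  d1 <- as.integer(p1[3]); d2 <- as.integer(p2[3])
  pdEq <- p1[1] == p2[1]
  pnEq <- p1[2] == p2[2]          # "NA" literal compares equal to "NA"
  if (d1 != d2) {
    hapCompat <- pdEq && (pnEq || d1 == 0L || d2 == 0L)
    if (!hapCompat) return(NA_character_)
    ds <- sort(c(d1, d2))
    if (all(ds == c(0L, 1L))) return("del")
    if (all(ds == c(1L, 2L))) return("ins")
    return(NA_character_)          # 0 vs 2: confounded
  }
  if (!pdEq && pnEq) return("Pd")
  if (pdEq && !pnEq) return("Pn")
  if (!pdEq && !pnEq) return("PdPn")
  NA_character_                    # identical labels (cannot occur)
}

#' Classify a QTL from its significant state pairs
#'
#' Each significant pair contributes mechanism evidence only when it is
#' a clean contrast (see the six groups in [qtlGroups()]): dosage
#' evidence comes from 0-vs-1 (deletion) and 1-vs-2 (insertion)
#' contrasts on an equal haplotype background; allelic evidence from
#' equal-dose contrasts in exactly one (Pd or Pn) haplotype.  Dosage
#' evidence, when present, determines the group (deletion, insertion,
#' or both); otherwise single-haplotype evidence is preferred, and
#' both-haplotype contrasts are called "P. deltoides + P. nigra" only
#' when no single-haplotype contrast is significant (parsimony:
#' a both-haplotype contrast is expected whenever either single
#' haplotype has an effect).  Two leak guards keep mechanisms
#' separable: 0-vs-1 deletion contrasts are discounted when direct Pn
#' evidence exists, because the dose-0 state pools both Pn haplotypes
#' and inherits half of any Pn-allelic effect; and confounded pairs
#' (dose and haplotype both differing, or 0-vs-2, which mixes a
#' deletion with an insertion difference) carry no classification
#' weight.  A QTL whose significant pairs are all confounded is
#' "ambiguous".
#'
#' When `testedPairs` is supplied (as [combinedScan()] does), a
#' multiplicity floor is applied: a mechanism needs at least two
#' supporting significant pairs unless only one pair of its type was
#' testable at the QTL's markers.  Under Benjamini-Hochberg control a
#' strong QTL yields dozens of true discoveries and therefore an
#' expected handful of false ones; without the floor a single stray
#' pair could flip the mechanism label.
#'
#' @param sigPairs data.frame with columns `state1`, `state2` of
#'   significant pairs at the QTL's markers.
#' @param testedPairs optional data.frame of the same shape listing
#'   every tested pair at those markers (enables the multiplicity
#'   floor).
#' @return one of [qtlGroups()] or `"ambiguous"`.
#' @export
classifyQtl <- function(sigPairs, testedPairs = NULL) {
  stopifNot1(nrow(sigPairs) >= 1, "need at least one significant pair")
  ev <- mapply(classifyPair, sigPairs$state1, sigPairs$state2)
  ev <- ev[!is.na(ev)]
  if (!is.null(testedPairs) && length(ev)) {
    tested <- mapply(classifyPair, testedPairs$state1, testedPairs$state2)
    tested <- table(tested[!is.na(tested)])
    sig <- table(ev)
    weak <- names(sig)[sig < 2 &
                         as.vector(tested[names(sig)]) > 1]
    ev <- ev[!ev %in% weak]
  }
  ## the dose-0 state pools both Pn haplotypes, so a pure Pn-haplotype
  ## effect leaks into 0-vs-1 contrasts at half strength; when direct
  ## Pn evidence is present, 0-vs-1 pairs are explainable by it and
  ## carry no deletion weight (the converse leak cannot occur: under a
  ## pure deletion effect all equal-dose pairs are null)
  if (any(ev == "Pn")) ev <- ev[ev != "del"]
  if (any(ev == "del") && any(ev == "ins")) return("deletion+insertion")
  if (any(ev == "del")) return("deletion")
  if (any(ev == "ins")) return("insertion")
  if (any(ev == "Pd") && any(ev == "Pn")) return("P. deltoides + P. nigra")
  if (any(ev == "Pd")) return("P. deltoides")
  if (any(ev == "Pn")) return("P. nigra")
  if (any(ev == "PdPn")) return("P. deltoides + P. nigra")
  "ambiguous"
}

## Adjusted R^2 of the trait on the state factor at the peak marker(s).
stateVarianceExplained <- function(y, states) {
  cc <- !is.na(y) & !is.na(states)
  f <- factor(states[cc])
  if (nlevels(f) < 2 || sum(cc) < nlevels(f) + 2) return(NA_real_)
  summary(lm(y[cc] ~ f))$adj.r.squared
}

#' Combined-state QTL scan for one trait
#'
#' Runs [pairwiseStateTests()] at every marker, adjusts p-values with
#' Benjamini-Hochberg (by default one family per comparison pair across
#' all markers genome-wide; alternatively per marker across its pairs),
#' merges markers with any significant pair into QTLs by adjacency,
#' classifies each QTL with [classifyQtl()], and attaches the variance
#' explained by the state factor at the QTL's peak marker.
#'
#' @param cm a [CommonMarkers-class] object.
#' @param pheno phenotype data.frame (`line_id` + trait columns).
#' @param trait trait name.
#' @param nPerm permutations per pair test.
#' @param alpha significance level on adjusted p-values.
#' @param minGroup minimum lines per state.
#' @param seed optional integer seed (per-marker substreams).
#' @param bhScope adjustment family:
#'   `"per-pair-across-markers"` (default) or
#'   `"per-marker-across-pairs"`.
#' @return list with `pairs` (all tests with `p_adj`) and `qtls`
#'   (one row per QTL, [writeQtlResults()]-ready; `peak_stat` is the
#'   smallest adjusted p at the peak marker and `threshold` is `alpha`).
#' @export
combinedScan <- function(cm, pheno, trait, nPerm = 1000, alpha = 0.05,
                         minGroup = 5, seed = NULL,
                         bhScope = c("per-pair-across-markers",
                                     "per-marker-across-pairs")) {
  bhScope <- match.arg(bhScope)
  lines <- lineIds(cm)
  stopifNot1(trait %in% names(pheno), "trait '%s' not in phenotypes", trait)
  y <- pheno[[trait]][match(lines, pheno$line_id)]
  st <- assignStates(cm)
  mk <- cm@markers

  acc <- list()
  for (m in seq_len(nrow(mk))) {
    pt <- pairwiseStateTests(y, st[m, ], nPerm, minGroup,
                             seed = if (is.null(seed)) NULL else
                               stageSeed(seed + m, "pair_perm"))
    if (nrow(pt)) acc[[length(acc) + 1]] <- cbind(
      marker = mk$marker_id[m], marker_idx = m, pt,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(acc)) do.call(rbind, acc) else
    data.frame(marker = character(), marker_idx = integer(),
               state1 = character(), state2 = character(), n1 = integer(),
               n2 = integer(), diff = numeric(), p_raw = numeric(),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  if (nrow(pairs)) {
    fam <- if (bhScope == "per-pair-across-markers")
      paste(pairs$state1, pairs$state2) else pairs$marker
    pairs$p_adj <- NA_real_
    for (f in unique(fam)) {
      i <- fam == f
      pairs$p_adj[i] <- bhAdjust(pairs$p_raw[i])
    }
  } else pairs$p_adj <- numeric(0)

  sigIdx <- sort(unique(pairs$marker_idx[pairs$p_adj < alpha]))
  if (!length(sigIdx)) {
    return(list(pairs = pairs, qtls = emptyQtlFrame()))
  }
  newRun <- c(TRUE, diff(sigIdx) > 1 |
                mk$chrom[sigIdx[-1]] != mk$chrom[sigIdx[-length(sigIdx)]])
  runs <- unname(split(sigIdx, cumsum(newRun)))
  qrows <- lapply(runs, function(i) {
    sp <- pairs[pairs$marker_idx %in% i & pairs$p_adj < alpha, ]
    tp <- pairs[pairs$marker_idx %in% i, ]
    pAtMarker <- tapply(sp$p_adj, sp$marker_idx, min)
    peak <- as.integer(names(pAtMarker)[which.min(pAtMarker)])
    data.frame(
      trait = trait, channel_or_group = classifyQtl(sp, tp),
      chrom = mk$chrom[peak],
      start_marker = mk$marker_id[i[1]],
      end_marker = mk$marker_id[i[length(i)]],
      peak_marker = mk$marker_id[peak],
      peak_stat = min(pAtMarker),
      significance = "significant",
      threshold = alpha,
      variance_explained = stateVarianceExplained(y, st[peak, ]),
      stringsAsFactors = FALSE)
  })
  qtls <- do.call(rbind, qrows)
  qtls$members <- lapply(runs, function(i) mk$marker_id[i])
  rownames(qtls) <- NULL
  list(pairs = pairs, qtls = qtls)
}
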