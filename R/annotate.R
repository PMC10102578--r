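#' Load the bundled (or a user-supplied) compound library
#'
#' The bundled library covers breath metabolites of the pathways and chemical
#' families relevant to allergic-asthma breath profiling (lysine degradation,
#' tyrosine metabolism, 2-oxocarboxylic acid metabolism, arginine pathways,
#' linoleic acid metabolism, plus aldehyde / fatty-acid / amide / sugar family
#' tags). Neutral monoisotopic masses are recomputed from the formulas.
#'
#' @param path Optional path to a TSV with columns `compound`, `formula`,
#'   `pathways` (semicolon-separated). Defaults to the bundled table.
#' @return data.frame with columns `compound`, `formula`, `pathways` (list
#'   column of character vectors) and `neutral_mass` (u).
#' @export
load_compound_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compound_library.tsv", package = "breathsig",
                        mustWork = TRUE)
  lib <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("compound", "formula", "pathways") %in% names(lib)))
  lib$pathways <- strsplit(lib$pathways, ";", fixed = TRUE)
  lib$neutral_mass <- vapply(lib$formula, monoisotopic_mass, 0)
  lib
}

#' Pathway definitions derived from a compound library
#'
#' @param library A compound library from [load_compound_library()].
#' @return Named list of data.frames (one per pathway) with columns
#'   `compound`, `formula`, `neutral_mass`.
#' @export
library_pathways <- function(library = load_compound_library()) {
  tags <- sort(unique(unlist(library$pathways)))
  out <- lapply(tags, function(tg) {
    sel <- vapply(library$pathways, function(p) tg %in% p, TRUE)
    library[sel, c("compound", "formula", "neutral_mass")]
  })
  names(out) <- tags
  out
}

#' Match measured feature m/z values against a compound library
#'
#' Every (compound, adduct) pair of the matching polarity whose theoretical
#' m/z lies within `tol_ppm` of a measured feature becomes a candidate,
#' sorted by absolute ppm error. Candidates carry the `exact_mass_only`
#' evidence flag unless the caller supplies stronger evidence later.
#'
#' @param feature_mzs Numeric vector of measured m/z values (Th).
#' @param polarity `"pos"` or `"neg"` (scalar or per-feature vector).
#' @param library Compound library data.frame (see [load_compound_library()]).
#' @param tol_ppm Match tolerance in ppm (default 15, just above the largest
#'   mass error retained in the reference annotation workflow).
#' @return List of annotation records, one per feature: list with `mz`,
#'   `polarity`, `candidates` (data.frame: compound, formula, adduct,
#'   theoretical_mz, ppm_error), `evidence`, `id_level`, `pathways`.
#' @export
match_features <- function(feature_mzs, polarity, library = load_compound_library(),
                           tol_ppm = 15) {
  stopifnot(is.numeric(feature_mzs), tol_ppm >= 0)
  polarity <- rep_len(match.arg(polarity, c("pos", "neg"), several.ok = TRUE),
                      length(feature_mzs))
  rules <- adduct_rules()
  # theoretical m/z for all compound x rule pairs, per polarity
  theo <- lapply(c(pos = "pos", neg = "neg"), function(pol) {
    rl <- rules[rules$polarity == pol, ]
    if (!nrow(library)) {
      return(data.frame(compound = character(), formula = character(),
                        adduct = character(), theoretical_mz = numeric()))
    }
    data.frame(
      compound = rep(library$compound, times = nrow(rl)),
      formula = rep(library$formula, times = nrow(rl)),
      adduct = rep(rl$name, each = nrow(library)),
      theoretical_mz = rep(library$neutral_mass, times = nrow(rl)) +
        rep(rl$mass_delta, each = nrow(library)),
      stringsAsFactors = FALSE
    )
  })
  pw_of <- function(cmp) {
    sel <- match(cmp, library$compound)
    sort(unique(unlist(library$pathways[sel])))
  }
  lapply(seq_along(feature_mzs), function(i) {
    tt <- theo[[polarity[i]]]
    ppm <- (feature_mzs[i] - tt$theoretical_mz) / tt$theoretical_mz * 1e6
    keep <- which(abs(ppm) <= tol_ppm)
    keep <- keep[order(abs(ppm[keep]))]
    cand <- tt[keep, , drop = FALSE]
    cand$ppm_error <- ppm[keep]
    rownames(cand) <- NULL
    flags <- if (nrow(cand)) "exact_mass_only" else character()
    list(
      mz = feature_mzs[i], polarity = polarity[i], candidates = cand,
      evidence = flags,
      id_level = if (length(flags)) assign_id_level(flags) else NA_integer_,
      pathways = if (nrow(cand)) pw_of(unique(cand$compound)) else character()
    )
  })
}

#' Schymanski-style identification confidence level from evidence flags
#'
#' Precedence: confirmed reference standard (1), spectral library MS2 match
#' (2), in-silico MS2 candidate (3), formula only (4), exact mass only (5).
#'
#' @param evidence_flags Character vector, subset of `standard_confirmed`,
#'   `library_ms2_match`, `insilico_ms2_candidate`, `formula_only`,
#'   `exact_mass_only`.
#' @return Integer level 1-5.
#' @export
assign_id_level <- function(evidence_flags) {
  valid <- c("standard_confirmed", "library_ms2_match", "insilico_ms2_candidate",
             "formula_only", "exact_mass_only")
  stopifnot(length(evidence_flags) >= 1L, all(evidence_flags %in% valid))
  if ("standard_confirmed" %in% evidence_flags) return(1L)
  if ("library_ms2_match" %in% evidence_flags) return(2L)
  if ("insilico_ms2_candidate" %in% evidence_flags) return(3L)
  if ("formula_only" %in% evidence_flags) return(4L)
  5L
}

#' Enumerate CHNOS molecular formulas matching a neutral mass
#'
#' Bounded exhaustive search over C 0-40, H 0-80, N 0-6, O 0-10, S 0-2 with
#' chemical filters: ring-plus-double-bond equivalents >= 0, integer RDBE
#' (nitrogen rule for even-electron neutrals) and H/C <= 3.1 (applied when
#' C > 1; single-carbon and carbon-free molecules such as urea are exempt
#' from the ratio heuristic). Results are sorted by absolute ppm deviation.
#'
#' @param neutral_mass Target neutral monoisotopic mass (u), in (0, 600].
#' @param tol_ppm Tolerance in ppm.
#' @return Character vector of formulas (e.g. `"C5H8O4"`), best match first.
#' @export
formula_candidates <- function(neutral_mass, tol_ppm = 5) {
  stopifnot(neutral_mass > 0, neutral_mass <= 600, tol_ppm >= 0)
  m <- element_masses()
  tol_u <- neutral_mass * tol_ppm * 1e-6
  grid <- expand.grid(C = 0:40, N = 0:6, O = 0:10, S = 0:2)
  base <- grid$C * m["C"] + grid$N * m["N"] + grid$O * m["O"] + grid$S * m["S"]
  # admissible H count range for each CNOS combination
  h_lo <- ceiling((neutral_mass - tol_u - base) / m["H"])
  h_hi <- floor((neutral_mass + tol_u - base) / m["H"])
  out_f <- character(); out_ppm <- numeric()
  idx <- which(h_hi >= pmax(0, h_lo) & h_lo <= 80)
  for (i in idx) {
    for (h in max(0, h_lo[i]):min(80, h_hi[i])) {
      C <- grid$C[i]; N <- grid$N[i]; O <- grid$O[i]; S <- grid$S[i]
      rdbe <- C + 1 + (N - h) / 2
      if (rdbe < 0 || rdbe != floor(rdbe)) next
      # H/C ratio heuristic targets carbon skeletons; C<=1 molecules
      # (e.g. urea, H/C = 4) are exempt
      if (C > 1 && h / C > 3.1) next
      mass <- base[i] + h * m["H"]
      ppm <- (mass - neutral_mass) / neutral_mass * 1e6
      if (abs(ppm) > tol_ppm) next
      out_f <- c(out_f, .format_formula(C, h, N, O, S))
      out_ppm <- c(out_ppm, ppm)
    }
  }
  out_f[order(abs(out_ppm))]
}

.format_formula <- function(C, H, N, O, S) {
  part <- function(sym, n) {
    if (n == 0) "" else if (n == 1) sym else paste0(sym, n)
  }
  paste0(part("C", C), part("H", H), part("N", N), part("O", O), part("S", S))
}

#' Group features related by isotope, adduct, or neutral-loss mass deltas
#'
#' Feature pairs whose m/z difference matches one of the standard deltas
#' (13C spacing, H2O, NH3, CO, CO2, HCOOH) within `tol_mTh` AND whose
#' cross-sample intensity profiles correlate at Pearson r >= `min_corr`
#' are linked; connected components form satellite groups, with the most
#' intense member flagged as the primary ion.
#'
#' @param matrix samples x features intensity matrix (any monotone scale).
#' @param feature_mzs m/z per column of `matrix`.
#' @param delta_table Named numeric vector of deltas (u); default the
#'   standard six.
#' @param tol_mTh Delta match tolerance in milli-Th.
#' @param min_corr Minimum Pearson correlation across samples.
#' @return data.frame with columns `feature` (column index), `mz`, `group`
#'   (group id, NA if unrelated to any other feature), `is_primary`,
#'   `relation` (delta name linking the feature to the group's primary,
#'   `"primary"` for the primary itself).
#' @export
group_related_features <- function(matrix, feature_mzs,
                                   delta_table = .mass_deltas(),
                                   tol_mTh = 5, min_corr = 0.9) {
  stopifnot(nrow(matrix) >= 3, ncol(matrix) == length(feature_mzs))
  p <- length(feature_mzs)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairs <- list()
  ord <- order(feature_mzs)
  tol <- tol_mTh / 1000
  maxd <- max(delta_table) + tol
  for (a in seq_len(p - 1)) {
    i <- ord[a]
    for (b in (a + 1):p) {
      j <- ord[b]
      d <- feature_mzs[j] - feature_mzs[i]
      if (d > maxd) break
      hit <- which(abs(delta_table - d) <= tol)
      if (!length(hit)) next
      r <- suppressWarnings(stats::cor(matrix[, i], matrix[, j]))
      if (is.na(r) || r < min_corr) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      pairs[[length(pairs) + 1L]] <- list(i = i, j = j,
                                          relation = names(delta_table)[hit[1]])
    }
  }
  root <- vapply(seq_len(p), find, 0L)
  grouped <- root %in% root[duplicated(root)]
  gid <- match(root, unique(root[grouped]))
  peak_height <- apply(matrix, 2, function(x) mean(x, na.rm = TRUE))
  is_primary <- rep(FALSE, p)
  relation <- rep(NA_character_, p)
  for (g in stats::na.omit(unique(gid))) {
    members <- which(!is.na(gid) & gid == g)
    prim <- members[which.max(peak_height[members])]
    is_primary[prim] <- TRUE
    relation[prim] <- "primary"
    for (pr in pairs) {
      for (k in c(pr$i, pr$j)) {
        if (k %in% members && k != prim && is.na(relation[k]))
          relation[k] <- pr$relation
      }
    }
    relation[members][is.na(relation[members])] <- "linked"
  }
  data.frame(feature = seq_len(p), mz = feature_mzs, group = gid,
             is_primary = is_primary, relation = relation,
             stringsAsFactors = FALSE)
}

#' Mummichog-style pathway enrichment on m/z features
#'
#' Maps every detected feature to library compounds via the adduct rules,
#' counts distinct compounds of each pathway hit by the significant feature
#' set, and compares against draws of equally many features from the full
#' detected set: `p = (1 + #{permutations with hits >= observed}) /
#' (n_perm + 1)`.
#'
#' @param sig_mzs Significant feature m/z values (subset of `all_mzs`).
#' @param all_mzs All detected feature m/z values.
#' @param polarity Scalar or per-feature polarity for `all_mzs` (`"pos"`/
#'   `"neg"`); `sig_mzs` inherit by position match.
#' @param pathways Named list of pathway member tables (see
#'   [library_pathways()]).
#' @param library Compound library used for the m/z -> compound mapping.
#' @param tol_ppm Mapping tolerance (ppm).
#' @param n_perm Number of permutation draws.
#' @param seed Integer seed for the permutation null.
#' @return data.frame: pathway, n_compounds (mappable from `all_mzs`),
#'   hits (observed from significant set), p_value, flag (`"no_mappable"`
#'   when nothing in the detected set maps to the pathway). Sorted by p.
#' @export
enrich_pathways <- function(sig_mzs, all_mzs, polarity = "neg",
                            pathways = library_pathways(),
                            library = load_compound_library(),
                            tol_ppm = 15, n_perm = 1000, seed = 1L) {
  stopifnot(all(sig_mzs %in% all_mzs), n_perm >= 1)
  polarity <- rep_len(polarity, length(all_mzs))
  ann <- match_features(all_mzs, polarity, library, tol_ppm)
  feat_compounds <- lapply(ann, function(a) unique(a$candidates$compound))
  hits_of <- function(sel_idx, members) {
    length(intersect(unique(unlist(feat_compounds[sel_idx])), members))
  }
  sig_idx <- match(sig_mzs, all_mzs)
  n_all <- length(all_mzs); n_sig <- length(sig_idx)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n_all, n_sig), simplify = FALSE)
  res <- lapply(names(pathways), function(nm) {
    members <- pathways[[nm]]$compound
    mappable <- hits_of(seq_len(n_all), members)
    if (mappable == 0)
      return(data.frame(pathway = nm, n_compounds = 0L, hits = 0L,
                        p_value = 1, flag = "no_mappable",
                        stringsAsFactors = FALSE))
    obs <- hits_of(sig_idx, members)
    if (obs == 0 || n_sig == 0) {
      pv <- 1
    } else {
      ge <- vapply(perm_idx, function(ix) hits_of(ix, members) >= obs, TRUE)
      pv <- (1 + sum(ge)) / (n_perm + 1)
    }
    data.frame(pathway = nm, n_compounds = mappable, hits = obs,
               p_value = pv, flag = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res[order(res$p_value, -res$hits), ]
}
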