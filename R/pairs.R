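#' Aggregate oligogenic combination records into positive gene pairs
#'
#' Keeps two-gene variant combinations with at least `min_level` evidence
#' and aggregates them at the gene-pair level, weighting each pair by the
#' maximum evidence weight over its contributing records. The default
#' evidence-level weights (weak 0.25, moderate 0.5, strong 1.0) are
#' configurable.
#'
#' @param records data.frame with columns `id`, `genes` (pipe-delimited
#'   gene ids or a list column), `level` (`weak`/`moderate`/`strong`),
#'   optionally `date` (first publication date, `Date` or string) and
#'   `disease`.
#' @param level_weights named numeric weights per evidence level.
#' @param min_level minimum evidence level retained.
#' @return data.frame of labelled pairs: `gene_a`, `gene_b` (lexicographic),
#'   `label` (`disease-causing`), `weight`, `level` (highest contributing),
#'   `date` (earliest associated date).
#' @export
aggregate_positive_pairs <- function(records,
                                     level_weights = c(weak = 0.25,
                                                       moderate = 0.5,
                                                       strong = 1),
                                     min_level = "weak") {
  lev_rank <- c(weak = 1L, moderate = 2L, strong = 3L)
  stopifnot(all(records$level %in% names(lev_rank)),
            min_level %in% names(lev_rank))
  genes <- if (is.list(records$genes)) records$genes
           else strsplit(as.character(records$genes), "|", fixed = TRUE)
  keep <- vapply(genes, function(g) length(unique(g)) == 2, logical(1)) &
    lev_rank[records$level] >= lev_rank[[min_level]]
  if (!any(keep))
    return(data.frame(gene_a = character(), gene_b = character(),
                      label = character(), weight = numeric(),
                      level = character(),
                      date = as.Date(character())))
  genes <- genes[keep]
  rec <- records[keep, , drop = FALSE]
  a <- vapply(genes, function(g) min(unique(g)), character(1))
  b <- vapply(genes, function(g) max(unique(g)), character(1))
  dates <- if ("date" %in% names(rec)) as.Date(rec$date)
           else rep(as.Date(NA), nrow(rec))
  key <- paste(a, b, sep = "\r")
  sp <- split(seq_along(key), key)
  out <- data.frame(
    gene_a = vapply(sp, function(i) a[i[1]], character(1)),
    gene_b = vapply(sp, function(i) b[i[1]], character(1)),
    label = "disease-causing",
    weight = vapply(sp, function(i)
      max(level_weights[rec$level[i]]), numeric(1)),
    level = vapply(sp, function(i)
      names(lev_rank)[max(lev_rank[rec$level[i]])], character(1)),
    stringsAsFactors = FALSE)
  out$date <- as.Date(vapply(sp, function(i)
    if (all(is.na(dates[i]))) NA_character_
    else as.character(min(dates[i], na.rm = TRUE)), character(1)))
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Hold out recent, confident, gene-disjoint test pairs
#'
#' Scans pairs from the most recently published to the oldest and accepts a
#' pair when its evidence level is at least moderate and neither gene
#' occurs in an already accepted pair, until `k` pairs are selected (or the
#' eligible pairs are exhausted).
#'
#' @param pairs output of [aggregate_positive_pairs()] (needs `level` and
#'   `date`).
#' @param k number of test pairs (default 15).
#' @return list with elements `test` and `train`, both data.frames.
#' @export
select_holdout_pairs <- function(pairs, k = 15) {
  lev_rank <- c(weak = 1L, moderate = 2L, strong = 3L)
  ord <- order(pairs$date, decreasing = TRUE, na.last = TRUE)
  used <- character()
  take <- logical(nrow(pairs))
  for (i in ord) {
    if (sum(take) >= k) break
    if (lev_rank[[pairs$level[i]]] < 2L) next
    gs <- c(pairs$gene_a[i], pairs$gene_b[i])
    if (any(gs %in% used)) next
    take[i] <- TRUE
    used <- c(used, gs)
  }
  list(test = pairs[take, , drop = FALSE],
       train = pairs[!take, , drop = FALSE])
}

#' Build the neutral gene-pair set from healthy-cohort variants
#'
#' Pipeline over per-individual variant records: (1) drop variants with
#' minor allele frequency above `max_maf`; (2) collapse variants per
#' individual and gene keeping the maximum deleteriousness (CADD-scale)
#' score; (3) form all gene pairs within each individual; (4) keep pairs
#' carried by at least `min_carriers` individuals; (5) require the pair's
#' maximum score to exceed `min_pair_score`; (6) keep pairs on different
#' chromosomes or at least `min_distance_bp` apart; (7) score each pair by
#' the mean over carriers of the smaller of the two gene scores, rank
#' decreasingly and keep the top `target_ratio * n_positive`; weights
#' follow [assign_pair_weights()] on the scores.
#'
#' @param variants data.frame with columns `individual`, `gene`, `chrom`,
#'   `pos`, `maf`, `score`.
#' @param gene_coords data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (used for the genomic-distance gate; distance is measured
#'   between the closest gene boundaries).
#' @param max_maf minor-allele-frequency ceiling (default 0.03).
#' @param min_carriers minimum number of carrier individuals (default 50).
#' @param min_pair_score minimum pair maximum score (default 3.57).
#' @param min_distance_bp minimum genomic separation on the same
#'   chromosome (default 10000).
#' @param target_ratio neutral-to-positive imbalance ratio (default 100).
#' @param n_positive size of the positive set the ratio refers to.
#' @return data.frame of ranked neutral pairs: `gene_a`, `gene_b`, `label`
#'   (`neutral`), `score`, `weight`, `n_carriers`.
#' @export
build_neutral_pairs <- function(variants, gene_coords, max_maf = 0.03,
                                min_carriers = 50, min_pair_score = 3.57,
                                min_distance_bp = 10000, target_ratio = 100,
                                n_positive = NULL) {
  v <- variants[variants$maf <= max_maf, , drop = FALSE]
  if (!nrow(v)) return(.empty_neutral())
  # per individual, per gene: max score
  key <- paste(v$individual, v$gene, sep = "\r")
  sp <- split(seq_len(nrow(v)), key)
  ind <- vapply(sp, function(i) v$individual[i[1]], character(1))
  gene <- vapply(sp, function(i) v$gene[i[1]], character(1))
  gscore <- vapply(sp, function(i) max(v$score[i]), numeric(1))
  # pairs within individuals
  pl <- split(seq_along(ind), ind)
  pa <- character(); pb <- character(); pmin_s <- numeric(); pmax_s <- numeric()
  for (ii in pl) {
    if (length(ii) < 2) next
    cmb <- utils::combn(ii, 2)
    g1 <- gene[cmb[1, ]]; g2 <- gene[cmb[2, ]]
    s1 <- gscore[cmb[1, ]]; s2 <- gscore[cmb[2, ]]
    swap <- g1 > g2
    tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
    pa <- c(pa, g1); pb <- c(pb, g2)
    pmin_s <- c(pmin_s, pmin(s1, s2)); pmax_s <- c(pmax_s, pmax(s1, s2))
  }
  if (!length(pa)) return(.empty_neutral())
  key <- paste(pa, pb, sep = "\r")
  sp <- split(seq_along(key), key)
  carriers <- vapply(sp, length, integer(1))
  keep <- carriers >= min_carriers
  sp <- sp[keep]
  if (!length(sp)) return(.empty_neutral())
  ga <- vapply(sp, function(i) pa[i[1]], character(1))
  gb <- vapply(sp, function(i) pb[i[1]], character(1))
  maxs <- vapply(sp, function(i) max(pmax_s[i]), numeric(1))
  score <- vapply(sp, function(i) mean(pmin_s[i]), numeric(1))
  ncar <- vapply(sp, length, integer(1))
  keep <- maxs > min_pair_score
  # genomic separation gate
  gc <- gene_coords
  ca <- gc$chrom[match(ga, gc$gene)]; cb <- gc$chrom[match(gb, gc$gene)]
  sa <- gc$start[match(ga, gc$gene)]; ea <- gc$end[match(ga, gc$gene)]
  sb <- gc$start[match(gb, gc$gene)]; eb <- gc$end[match(gb, gc$gene)]
  gap <- pmax(sa, sb) - pmin(ea, eb)  # negative when overlapping
  far <- is.na(ca) | is.na(cb) | ca != cb | gap >= min_distance_bp
  keep <- keep & far
  ga <- ga[keep]; gb <- gb[keep]; score <- score[keep]; ncar <- ncar[keep]
  if (!length(ga)) return(.empty_neutral())
  ord <- order(-score, ga, gb)
  ga <- ga[ord]; gb <- gb[ord]; score <- score[ord]; ncar <- ncar[ord]
  if (!is.null(n_positive)) {
    top <- min(length(ga), target_ratio * n_positive)
    ga <- ga[seq_len(top)]; gb <- gb[seq_len(top)]
    score <- score[seq_len(top)]; ncar <- ncar[seq_len(top)]
  }
  data.frame(gene_a = ga, gene_b = gb, label = "neutral", score = score,
             weight = assign_pair_weights(score), n_carriers = ncar,
             stringsAsFactors = FALSE, row.names = NULL)
}

.empty_neutral <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             label = character(), score = numeric(), weight = numeric(),
             n_carriers = integer())
}

#' Map pair scores to confidence weights
#'
#' Monotone min-max normalization of the scores into `(0, 1]` with floor
#' `eps`; constant scores all map to 1.
#'
#' @param scores numeric vector.
#' @param eps weight floor (default 0.05).
#' @return numeric weights in `(0, 1]`, order-consistent with `scores`.
#' @export
assign_pair_weights <- function(scores, eps = 0.05) {
  if (!length(scores)) return(numeric())
  rng <- range(scores)
  if (diff(rng) == 0) return(rep(1, length(scores)))
  eps + (1 - eps) * (scores - rng[1]) / diff(rng)
}
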