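#' Label connected components of a binary mask
#'
#' 4- or 8-connected component labelling. The 4-connected labelling is
#' delegated to `EBImage::bwlabel`; 8-connectivity is obtained by merging
#' 4-components that touch diagonally (union-find over the label adjacency
#' graph), which gives exactly the 8-connected partition.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background), labels densely
#'   renumbered 1..n in first-pixel order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mode(mask) <- "logical"
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  if (connectivity == 8) {
    nr <- nrow(lab); nc <- ncol(lab)
    # pairs of distinct labels that are diagonal neighbours
    pairs <- rbind(
      diag_pairs(lab[-nr, -nc], lab[-1, -1]),   # down-right
      diag_pairs(lab[-nr, -1], lab[-1, -nc])    # down-left
    )
    if (nrow(pairs) > 0) {
      n <- max(lab)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0] <- root[lab[lab > 0]]
    }
  }
  # dense renumbering in first-occurrence (column-major) order
  nz <- lab[lab > 0]
  lab[lab > 0] <- match(nz, unique(nz))
  lab
}

diag_pairs <- function(a, b) {
  sel <- a > 0 & b > 0 & a != b
  if (!any(sel)) return(matrix(integer(0), 0, 2))
  unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
}

#' Extract candidate colonies from a flagged-pixel mask
#'
#' Groups flagged pixels into connected components, merges components whose
#' centroids lie within `merge_radius` pixels of each other (single linkage),
#' and drops components smaller than `min_pixels`. Each surviving group is a
#' retrieval candidate whose guano area is exactly 900 m^2 per pixel.
#'
#' @param guano_mask Logical matrix of flagged pixels.
#' @param connectivity 4 or 8 (default 8).
#' @param merge_radius Centroid-distance merge radius in pixels (0 = never).
#' @param min_pixels Minimum component size kept (default 1; the smallest
#'   real detected colony was a single-pixel footprint, so filtering is left
#'   to downstream stages).
#' @param scene_id Identifier copied onto each candidate.
#' @return `data.frame` of class `retrieval_candidates`: `candidate_id`,
#'   `scene_id`, `pixel_count`, `guano_area` (m^2), `centroid_x`,
#'   `centroid_y` (scene-local metres).
#' @export
extract_candidates <- function(guano_mask, connectivity = 8, merge_radius = 0,
                               min_pixels = 1, scene_id = "scene-1") {
  lab <- label_components(guano_mask, connectivity)
  empty <- data.frame(candidate_id = character(), scene_id = character(),
                      pixel_count = integer(), guano_area = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("retrieval_candidates", "data.frame")
  n <- max(lab)
  if (n == 0) return(empty)

  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  cnt <- tabulate(lv, n)
  # pixel-centre coordinates in metres: x along columns, y along rows
  cx <- tapply((idx[, 2] - 0.5) * PIXEL_SIZE, lv, mean)
  cy <- tapply((idx[, 1] - 0.5) * PIXEL_SIZE, lv, mean)

  group <- seq_len(n)
  if (merge_radius > 0 && n > 1) {
    d <- as.matrix(stats::dist(cbind(cx, cy))) / PIXEL_SIZE
    find <- function(i) { while (group[i] != i) { group[i] <<- group[group[i]]; i <- group[i] }; i }
    close <- which(d <= merge_radius & upper.tri(d), arr.ind = TRUE)
    for (k in seq_len(nrow(close))) {
      a <- find(close[k, 1]); b <- find(close[k, 2])
      if (a != b) group[max(a, b)] <- min(a, b)
    }
    group <- vapply(seq_len(n), find, integer(1))
  }
  g <- match(group, unique(group))
  ng <- max(g)
  gcnt <- as.numeric(tapply(cnt, g, sum))
  gx <- as.numeric(tapply(cx * cnt, g, sum)) / gcnt   # pixel-weighted centroid
  gy <- as.numeric(tapply(cy * cnt, g, sum)) / gcnt

  keep <- which(gcnt >= min_pixels)
  out <- data.frame(
    candidate_id = sprintf("%s-c%03d", scene_id, seq_along(keep)),
    scene_id = scene_id,
    pixel_count = as.integer(gcnt[keep]),
    guano_area = PIXEL_AREA * gcnt[keep],
    centroid_x = gx[keep], centroid_y = gy[keep],
    stringsAsFactors = FALSE)
  class(out) <- c("retrieval_candidates", "data.frame")
  out
}

#' Score retrieval candidates against a colony registry
#'
#' Reproduces the four-outcome comparison between an automated retrieval and
#' a reference survey. Each candidate is assigned greedily (closest pair
#' first) to the nearest registry colony within `max_match_distance`; a
#' colony with at least one assigned candidate is detected (`both`), extra
#' candidates at an already-confirmed colony are absorbed rather than
#' counted as false positives, unmatched colonies are omissions, and
#' unmatched candidates are commissions. The fourth outcome (no colony, no
#' candidate) is the background and is not enumerated. Detection is the
#' binary `M` of the missing-colony model: detected means `M = 1`.
#'
#' @param candidates A `retrieval_candidates` data frame.
#' @param registry A `colony_registry` data frame.
#' @param max_match_distance Maximum centre-to-centroid distance in metres
#'   (default 3000).
#' @return Object of class `match_outcomes`: list with `colonies` (registry
#'   plus `outcome` in `{both, omission}`, `detected` 0/1, `candidate_id`,
#'   `guano_area` of the matched candidate group), `commissions` (unmatched
#'   candidates), and `summary` (counts and the commission rate =
#'   commissions / candidates-after-matching).
#' @export
match_outcomes <- function(candidates, registry, max_match_distance = 3000) {
  if (max_match_distance <= 0) stop("max_match_distance must be > 0")
  ncand <- nrow(candidates); ncol_ <- nrow(registry)

  cand_match <- rep(NA_integer_, ncand)   # registry row for each candidate
  if (ncand > 0 && ncol_ > 0) {
    d <- outer(candidates$centroid_x, registry$x, "-")^2 +
         outer(candidates$centroid_y, registry$y, "-")^2
    d <- sqrt(d)
    ok <- which(d <= max_match_distance, arr.ind = TRUE)
    if (nrow(ok) > 0) {
      ord <- order(d[ok])
      for (k in ord) {
        ci <- ok[k, 1]
        if (is.na(cand_match[ci])) cand_match[ci] <- ok[k, 2]
      }
    }
  }

  detected <- tabulate(cand_match[!is.na(cand_match)], ncol_) > 0
  matched_area <- vapply(seq_len(ncol_), function(j) {
    rows <- which(cand_match == j)
    if (length(rows) == 0) NA_real_ else sum(candidates$guano_area[rows])
  }, numeric(1))
  matched_id <- vapply(seq_len(ncol_), function(j) {
    rows <- which(cand_match == j)
    if (length(rows) == 0) NA_character_ else candidates$candidate_id[rows[1]]
  }, character(1))

  colonies <- as.data.frame(registry)
  colonies$outcome <- ifelse(detected, "both", "omission")
  colonies$detected <- as.integer(detected)
  colonies$candidate_id <- matched_id
  colonies$guano_area <- matched_area

  commissions <- as.data.frame(candidates)[is.na(cand_match), , drop = FALSE]
  if (ncand > 0) commissions$outcome <- rep("commission", nrow(commissions))

  n_both <- sum(detected); n_om <- ncol_ - n_both
  n_comm <- nrow(commissions)
  n_cand_after <- n_both + n_comm   # matched candidate groups + commissions
  structure(list(
    colonies = colonies, commissions = commissions,
    summary = list(n_registry = ncol_, n_candidates = ncand,
                   n_both = n_both, n_omission = n_om,
                   n_commission = n_comm,
                   n_candidates_after_matching = n_cand_after,
                   commission_rate = if (n_cand_after > 0) n_comm / n_cand_after else NA_real_,
                   p_hat = if (ncol_ > 0) n_both / ncol_ else NA_real_)),
    class = "match_outcomes")
}

#' @export
print.match_outcomes <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<match_outcomes> %d colonies: %d detected (both), %d omissions; ",
                     "%d commissions of %d candidate groups (rate %.3f)\n"),
              s$n_registry, s$n_both, s$n_omission, s$n_commission,
              s$n_candidates_after_matching,
              ifelse(is.na(s$commission_rate), NaN, s$commission_rate)))
  invisible(x)
}
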