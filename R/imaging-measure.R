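# Intensity threshold for marker positivity / binarisation.
# "background": mean + 3 SD of pixels outside the given foreground mask
# (or of the dimmest half of the image when no mask is supplied);
# "otsu": Otsu's threshold on the rescaled channel.
channel_threshold <- function(img, method = c("background", "otsu"),
                              fg_mask = NULL) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(img)
    if (diff(rng) == 0) {
      return(Inf)
    }
    norm <- (img - rng[1]) / diff(rng)
    return(rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng))
  }
  if (!is.null(fg_mask)) {
    bg <- img[!fg_mask]
    if (length(bg) < 2L) {
      return(Inf)
    }
    return(mean(bg) + 3 * sd(bg))
  }
  # no mask: background dominates the field, so median/MAD are robust to
  # the foreground tail
  median(img) + 3 * stats::mad(img)
}

# Drop connected components smaller than `min_px` pixels.
clean_mask <- function(bw, min_px) {
  if (!any(bw)) {
    return(bw)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  keep <- which(tabulate(lab[lab > 0]) >= min_px)
  matrix(lab %in% keep, nrow(bw), ncol(bw))
}

#' Score marker positivity per cell region
#'
#' Measures the mean intensity of each marker channel inside every
#' expanded cell region and calls a region positive when that mean
#' strictly exceeds the channel threshold (default: background mean +
#' 3 SD, background = pixels outside all regions). Fractions follow the
#' cell-population conventions: Tubb3+/Ho over all traced cells, and
#' MAP2+, NeuN+ among Tubb3+ cells (neuronal maturation rates).
#'
#' @param regions A `cell_region_set` from [expand_regions()].
#' @param stack The [channel_stack()].
#' @param markers Channels to score (present ones are used).
#' @param threshold_method `"background"` or `"otsu"`.
#' @return List of class `marker_scores`: `cells` (per-region tibble with
#'   `mean_<marker>` and `<marker>_pos` columns) and `fractions` (one-row
#'   tibble: `tubb3_per_ho`, `map2_per_tubb3`, `neun_per_tubb3`; NA when
#'   a denominator is zero).
#' @export
score_markers <- function(regions, stack,
                          markers = c("tubb3", "map2", "neun"),
                          threshold_method = "background") {
  stopifnot(inherits(regions, "cell_region_set"))
  lab <- regions$labels
  ids <- regions$cells$label
  cells <- regions$cells["label"]
  if (length(ids) == 0L) {
    return(structure(
      list(
        cells = cells,
        fractions = tibble(
          tubb3_per_ho = undefined_metric(),
          map2_per_tubb3 = undefined_metric(),
          neun_per_tubb3 = undefined_metric()
        )
      ),
      class = "marker_scores"
    ))
  }
  fg <- lab > 0
  labf <- lab[fg]
  for (m in markers) {
    if (!has_channel(stack, m)) next
    img <- get_channel(stack, m)
    thr <- channel_threshold(img, threshold_method, fg_mask = fg)
    means <- tapply(img[fg], labf, mean)[as.character(ids)]
    cells[[paste0("mean_", m)]] <- as.numeric(means)
    cells[[paste0(m, "_pos")]] <- as.numeric(means) > thr
  }
  n_all <- nrow(cells)
  frac <- tibble(
    tubb3_per_ho = undefined_metric(),
    map2_per_tubb3 = undefined_metric(),
    neun_per_tubb3 = undefined_metric()
  )
  if ("tubb3_pos" %in% names(cells) && n_all > 0L) {
    frac$tubb3_per_ho <- mean(cells$tubb3_pos)
    n_t <- sum(cells$tubb3_pos)
    if (n_t > 0L) {
      if ("map2_pos" %in% names(cells)) {
        frac$map2_per_tubb3 <- sum(cells$map2_pos & cells$tubb3_pos) / n_t
      }
      if ("neun_pos" %in% names(cells)) {
        frac$neun_per_tubb3 <- sum(cells$neun_pos & cells$tubb3_pos) / n_t
      }
    }
  }
  structure(list(cells = cells, fractions = frac), class = "marker_scores")
}

# Zero-padded shift of a matrix by (dr, dc).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Morphological skeleton (Guo-Hall thinning)
#'
#' Iteratively thins a binary mask to a one-pixel-wide 8-connected
#' skeleton using the two-subiteration Guo-Hall algorithm (which, unlike
#' Zhang-Suen, does not leave two-pixel-wide diagonal lines), followed by
#' a staircase-corner cleanup so the result is a minimal 8-connected
#' path.
#'
#' @param mask Logical or 0/1 matrix.
#' @param max_iter Safety cap on iterations.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask, max_iter = 1000L) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north; matrix rows grow downward so
      # "north" is row - 1
      p2 <- shift_mat(m, 1, 0) # value of north neighbour at each pixel
      p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1)
      p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0)
      p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1)
      p9 <- shift_mat(m, 1, 1)
      cc <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      nn <- pmin(n1, n2)
      mm <- if (step == 1L) {
        (p6 | p7 | !p9) & p8
      } else {
        (p2 | p3 | !p5) & p4
      }
      cond <- m == 1 & cc == 1 & nn >= 2 & nn <= 3 & !mm
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  remove_staircase_px(m == 1L)
}

# Delete redundant corner pixels of 4-connected staircases: a skeleton
# pixel with exactly two neighbours that are themselves 8-adjacent can be
# removed without breaking connectivity, leaving a minimal 8-connected
# path whose chamfer length is orientation-consistent.
remove_staircase_px <- function(s) {
  idx <- which(s)
  nr <- nrow(s)
  coords <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, 1L]
    c <- coords[i, 2L]
    if (r <= 1L || c <= 1L || r >= nr || c >= ncol(s)) next
    if (!s[r, c]) next
    nbr <- s[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
    nbr[2L, 2L] <- FALSE
    if (sum(nbr) != 2L) next
    w <- which(nbr)
    dr <- (w - 1L) %% 3L
    dc <- (w - 1L) %/% 3L
    if (max(abs(dr[1L] - dr[2L]), abs(dc[1L] - dc[2L])) <= 1L) {
      s[r, c] <- FALSE
    }
  }
  s
}

# Chamfer length of a skeleton: count 4-adjacent and diagonal links with
# minimax weights (0.960, 1.358), which bound the straight-line error to
# about +/-4% at any orientation. A diagonal link is skipped when the two
# pixels share an orthogonal skeleton neighbour (staircase redundancy).
skeleton_length_px <- function(skel) {
  s <- matrix(skel > 0, nrow(skel), ncol(skel))
  nr <- nrow(s)
  nc <- ncol(s)
  n_orth <- sum(s[-1, ] & s[-nr, ]) + sum(s[, -1] & s[, -nc])
  # pairs (i,j)-(i+1,j+1), redundant if (i+1,j) or (i,j+1) is set
  d1 <- s[-nr, -nc] & s[-1, -1] & !s[-1, -nc] & !s[-nr, -1]
  # pairs (i+1,j)-(i,j+1), redundant if (i,j) or (i+1,j+1) is set
  d2 <- s[-1, -nc] & s[-nr, -1] & !s[-nr, -nc] & !s[-1, -1]
  0.960 * n_orth + 1.358 * (sum(d1) + sum(d2))
}

#' Total neurite length from the Tubb3 channel
#'
#' Binarises the Tubb3 channel, removes cell-body blobs by morphological
#' opening with a disc wider than any neurite (so only thin processes
#' remain), skeletonises the remaining mask and converts the chamfer path
#' length to micrometres.
#'
#' @param stack A [channel_stack()] with a Tubb3 channel.
#' @param soma_radius_um Opening radius used to reconstruct (and remove)
#'   cell bodies; must exceed the neurite half-width and be below the
#'   soma radius.
#' @param threshold_method `"background"` (default) or `"otsu"`.
#' @return Total neurite length (um); 0 for a blank channel.
#' @export
measure_neurite_length <- function(stack, soma_radius_um = 3,
                                   threshold_method = "background") {
  if (!has_channel(stack, "tubb3")) stop_invalid("Tubb3 channel required")
  img <- get_channel(stack, "tubb3")
  ps <- stack$pixel_size_um
  thr <- channel_threshold(img, threshold_method)
  bw <- img > thr
  if (!any(bw)) {
    return(0)
  }
  r_px <- max(1L, round(soma_radius_um / ps))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  somata <- EBImage::opening(EBImage::Image(bw), brush)
  neurites <- bw & !(EBImage::imageData(somata) > 0)
  neurites <- clean_mask(neurites, min_px = 25L) # noise specks and debris
  if (!any(neurites)) {
    return(0)
  }
  skel <- skeletonize(neurites)
  skeleton_length_px(skel) * ps
}

#' Synaptic area per micrometre of neurite
#'
#' Binarises the punctum channel (Synapsin I or PSD95), keeps only the
#' signal overlapping the Tubb3-stained area, and divides that area
#' (um^2) by the total Tubb3+ neurite length (um).
#'
#' @param stack A [channel_stack()] with the marker and Tubb3 channels.
#' @param marker `"syni"` or `"psd95"`.
#' @param threshold_method Binarisation rule for both channels.
#' @param soma_radius_um Forwarded to [measure_neurite_length()].
#' @return List: `area_um2` (marker area on Tubb3), `neurite_length_um`,
#'   `area_per_um` (NA when the neurite length is zero).
#' @export
synaptic_area_per_neurite <- function(stack, marker = c("syni", "psd95"),
                                      threshold_method = "background",
                                      soma_radius_um = 3) {
  marker <- match.arg(marker)
  if (!has_channel(stack, marker)) stop_invalid(sprintf("channel '%s' required", marker))
  if (!has_channel(stack, "tubb3")) stop_invalid("Tubb3 channel required")
  img <- get_channel(stack, marker)
  tub <- get_channel(stack, "tubb3")
  ps <- stack$pixel_size_um
  mk_bw <- clean_mask(img > channel_threshold(img, threshold_method), 5L)
  tb_bw <- clean_mask(tub > channel_threshold(tub, threshold_method), 25L)
  area <- sum(mk_bw & tb_bw) * ps^2
  len <- measure_neurite_length(stack,
    soma_radius_um = soma_radius_um,
    threshold_method = threshold_method
  )
  list(
    area_um2 = area,
    neurite_length_um = len,
    area_per_um = if (len > 0) area / len else undefined_metric()
  )
}

#' Fraction of CellROX-positive neurons
#'
#' Number of Tubb3+/CellROX+ cells divided by the number of Tubb3+ cells
#' (oxidative-stress readout; CellROX signal in Tubb3- cells is ignored
#' by construction).
#'
#' @param regions A `cell_region_set`.
#' @param stack The [channel_stack()] with Tubb3 and CellROX channels.
#' @param threshold_method Positivity rule per channel.
#' @return Scalar fraction; NA when no cell is Tubb3+.
#' @export
cellrox_fraction <- function(regions, stack, threshold_method = "background") {
  sc <- score_markers(regions, stack,
    markers = c("tubb3", "cellrox"),
    threshold_method = threshold_method
  )
  cells <- sc$cells
  if (!all(c("tubb3_pos", "cellrox_pos") %in% names(cells))) {
    stop_invalid("Tubb3 and CellROX channels required")
  }
  n_t <- sum(cells$tubb3_pos)
  if (n_t == 0L) {
    return(undefined_metric())
  }
  sum(cells$tubb3_pos & cells$cellrox_pos) / n_t
}
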