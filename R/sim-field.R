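#' Channel stack container
#'
#' A named set of equally-sized 2D intensity channels plus the pixel size.
#' Channel names are matched case-insensitively throughout the package
#' (canonical names: hoechst, tubb3, map2, neun, syni, psd95, cellrox,
#' mcherry).
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#' @param pixel_size_um Pixel edge length (um/px).
#' @return A list of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um) {
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop_invalid("all channels must share one shape")
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um),
    class = "channel_stack"
  )
}

get_channel <- function(stack, name) {
  stopifnot(inherits(stack, "channel_stack"))
  hit <- match(tolower(name), tolower(names(stack$channels)))
  if (is.na(hit)) stop_invalid(sprintf("channel '%s' not present", name))
  stack$channels[[hit]]
}

has_channel <- function(stack, name) {
  !is.na(match(tolower(name), tolower(names(stack$channels))))
}

#' Configuration for rendered immunofluorescence fields
#'
#' Parameters for [render_synthetic_field()]. The renderer emulates a
#' high-content field: Hoechst-stained elliptical nuclei (including small,
#' bright pyknotic nuclei), soma-filled marker channels whose positivity
#' labels are drawn per cell, nuclear mCherry, Tubb3-positive neurites
#' drawn as polylines of known length, and synaptic puncta placed on or
#' off neurites.
#'
#' @param seed Integer RNG seed.
#' @param width_px,height_px Field size (px).
#' @param pixel_size_um Pixel size (um/px).
#' @param n_cells Number of cells to place.
#' @param nucleus_area_um2_mean,nucleus_area_um2_sd Normal nucleus area
#'   distribution (um^2) for healthy nuclei.
#' @param pyknotic_fraction Fraction of pyknotic cells.
#' @param pyknotic_area_um2 Area of pyknotic nuclei (um^2, below the 50
#'   um^2 tracing cutoff).
#' @param pyknotic_brightness_factor Hoechst brightness multiplier of
#'   pyknotic vs typical nuclei.
#' @param p_tubb3 Probability a cell is Tubb3+ (a neuron).
#' @param p_map2,p_neun,p_cellrox Conditional positive probabilities among
#'   Tubb3+ cells.
#' @param p_mcherry Probability a cell is mCherry+ (nuclear signal).
#' @param n_neurites Number of neurites to draw (each attached to a
#'   random Tubb3+ cell; a neurite whose path cannot avoid other somata
#'   after `max_attempts` tries is skipped and excluded from the truth).
#' @param neurite_length_um Length of each neurite (um).
#' @param neurite_width_px Drawn neurite width (px).
#' @param n_syni,n_psd95 Punctum counts per marker.
#' @param punctum_radius_px Punctum disc radius (px).
#' @param puncta_on_neurite Place puncta on neurite centrelines (TRUE) or
#'   on background away from any Tubb3 signal (FALSE).
#' @param nucleus_intensity,marker_intensity Foreground intensities (a.u.).
#' @param background,noise_sd Background level and Gaussian noise SD.
#' @param max_attempts Placement retries per object before giving up.
#' @return A list of class `field_sim_config`.
#' @export
field_sim_config <- function(seed = 1L,
                             width_px = 600L, height_px = 600L,
                             pixel_size_um = 0.5,
                             n_cells = 60L,
                             nucleus_area_um2_mean = 85,
                             nucleus_area_um2_sd = 15,
                             pyknotic_fraction = 0.1,
                             pyknotic_area_um2 = 30,
                             pyknotic_brightness_factor = 2.5,
                             p_tubb3 = 0.8,
                             p_map2 = 0.6,
                             p_neun = 0.5,
                             p_cellrox = 0.25,
                             p_mcherry = 0.3,
                             n_neurites = 10L,
                             neurite_length_um = 60,
                             neurite_width_px = 5L,
                             n_syni = 40L,
                             n_psd95 = 40L,
                             punctum_radius_px = 2L,
                             puncta_on_neurite = TRUE,
                             nucleus_intensity = 0.5,
                             marker_intensity = 0.7,
                             background = 0.02,
                             noise_sd = 0.01,
                             max_attempts = 500L) {
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(width_px, "width_px")
  check_positive_scalar(height_px, "height_px")
  for (p in c("pyknotic_fraction", "p_tubb3", "p_map2", "p_neun",
              "p_cellrox", "p_mcherry")) {
    check_fraction(get(p), p)
  }
  check_nonnegative(nucleus_area_um2_mean, "nucleus_area_um2_mean")
  check_nonnegative(neurite_length_um, "neurite_length_um")
  structure(
    as.list(environment())[c(
      "seed", "width_px", "height_px", "pixel_size_um", "n_cells",
      "nucleus_area_um2_mean", "nucleus_area_um2_sd", "pyknotic_fraction",
      "pyknotic_area_um2", "pyknotic_brightness_factor", "p_tubb3", "p_map2",
      "p_neun", "p_cellrox", "p_mcherry", "n_neurites", "neurite_length_um",
      "neurite_width_px", "n_syni", "n_psd95", "punctum_radius_px",
      "puncta_on_neurite", "nucleus_intensity", "marker_intensity",
      "background", "noise_sd", "max_attempts"
    )],
    class = "field_sim_config"
  )
}

# Pixel index set of a rotated ellipse of given pixel area at (cy, cx).
ellipse_pixels <- function(cy, cx, area_px, aspect, theta, nrow, ncol) {
  b <- sqrt(area_px / (pi * aspect)) # minor semi-axis
  a <- aspect * b
  r <- ceiling(a) + 1L
  rows <- max(1L, floor(cy - r)):min(nrow, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(ncol, ceiling(cx + r))
  g <- expand.grid(row = rows, col = cols)
  dy <- g$row - cy
  dx <- g$col - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(g$row[keep], g$col[keep])
}

disc_pixels <- function(cy, cx, radius, nrow, ncol) {
  r <- ceiling(radius)
  rows <- max(1L, floor(cy - r)):min(nrow, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(ncol, ceiling(cx + r))
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= radius^2
  cbind(g$row[keep], g$col[keep])
}

# Pixel index set of a thick segment: discs stamped along the line.
segment_pixels <- function(y0, x0, y1, x1, width, nrow, ncol) {
  len <- sqrt((y1 - y0)^2 + (x1 - x0)^2)
  n <- max(2L, ceiling(len * 2))
  tt <- seq(0, 1, length.out = n)
  pts <- unique(round(cbind(y0 + tt * (y1 - y0), x0 + tt * (x1 - x0))))
  px <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    disc_pixels(pts[i, 1], pts[i, 2], width / 2, nrow, ncol)
  }))
  unique(px)
}

#' Render a synthetic immunofluorescence field
#'
#' Generates a multichannel field with full ground truth: per-cell
#' centroids, nucleus areas, pyknotic flags and marker labels; total drawn
#' neurite length; and rendered synaptic punctum areas (both total and
#' the part overlapping Tubb3 signal).
#'
#' @param config A [field_sim_config()].
#' @return A list of class `field_sim` with `stack` (a [channel_stack()]),
#'   `truth` (list: `cells` tibble, `neurite_length_um`,
#'   `n_neurites_drawn`, `syni_area_um2`, `syni_on_tubb3_um2`,
#'   `psd95_area_um2`, `psd95_on_tubb3_um2`), and `config`.
#' @export
render_synthetic_field <- function(config) {
  stopifnot(inherits(config, "field_sim_config"))
  with_seed(config$seed, {
    nr <- config$height_px
    nc <- config$width_px
    ps <- config$pixel_size_um

    blank <- function() matrix(0, nr, nc)
    ch <- list(
      hoechst = blank(), tubb3 = blank(), map2 = blank(), neun = blank(),
      cellrox = blank(), mcherry = blank(), syni = blank(), psd95 = blank()
    )

    # --- cells -----------------------------------------------------------
    n <- config$n_cells
    pyk <- runif(n) < config$pyknotic_fraction
    area_um2 <- ifelse(
      pyk,
      config$pyknotic_area_um2 * exp(rnorm(n, 0, 0.08)),
      pmax(55, rnorm(n, config$nucleus_area_um2_mean, config$nucleus_area_um2_sd))
    )
    area_px <- area_um2 / ps^2
    r_eq <- sqrt(area_px / pi)
    soma_r <- 1.35 * r_eq
    margin <- ceiling(max(soma_r)) + 2L
    min_sep <- 2 * max(soma_r) + 4

    centers <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(config$max_attempts)) {
        cy <- runif(1, margin, nr - margin)
        cx <- runif(1, margin, nc - margin)
        if (i == 1L ||
          all((centers[seq_len(i - 1), 1] - cy)^2 +
            (centers[seq_len(i - 1), 2] - cx)^2 > min_sep^2)) {
          centers[i, ] <- c(cy, cx)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rlang::warn("cell placement retries exhausted; field too crowded")
        stop_invalid("could not place all cells without overlap")
      }
    }

    tubb3 <- runif(n) < config$p_tubb3
    map2 <- tubb3 & runif(n) < config$p_map2
    neun <- tubb3 & runif(n) < config$p_neun
    crox <- tubb3 & runif(n) < config$p_cellrox
    mch <- runif(n) < config$p_mcherry

    rendered_area_px <- numeric(n)
    for (i in seq_len(n)) {
      px <- ellipse_pixels(
        centers[i, 1], centers[i, 2], area_px[i],
        aspect = runif(1, 1.0, 1.4), theta = runif(1, 0, pi), nr, nc
      )
      rendered_area_px[i] <- nrow(px)
      gain <- exp(rnorm(1, 0, 0.04))
      bright <- if (pyk[i]) config$pyknotic_brightness_factor else 1
      ch$hoechst[px] <- config$nucleus_intensity * bright * gain
      if (mch[i]) ch$mcherry[px] <- config$marker_intensity * gain
      soma <- disc_pixels(centers[i, 1], centers[i, 2], soma_r[i], nr, nc)
      if (tubb3[i]) ch$tubb3[soma] <- config$marker_intensity * gain
      if (map2[i]) ch$map2[soma] <- config$marker_intensity * gain
      if (neun[i]) ch$neun[soma] <- config$marker_intensity * gain
      if (crox[i]) ch$cellrox[soma] <- config$marker_intensity * gain
    }

    # --- neurites --------------------------------------------------------
    neur_len_total <- 0
    n_drawn <- 0L
    centreline <- list() # sampled centreline points for punctum placement
    neuron_idx <- which(tubb3)
    len_px <- config$neurite_length_um / ps
    if (config$n_neurites > 0L && length(neuron_idx) > 0L) {
      for (k in seq_len(config$n_neurites)) {
        drawn <- FALSE
        for (a in seq_len(config$max_attempts)) {
          i <- sample(neuron_idx, 1L)
          ang <- runif(1, 0, 2 * pi)
          y0 <- centers[i, 1] + soma_r[i] * sin(ang)
          x0 <- centers[i, 2] + soma_r[i] * cos(ang)
          # one mid-path bend to avoid perfectly straight fields
          bend <- ang + runif(1, -pi / 6, pi / 6)
          y1 <- y0 + 0.5 * len_px * sin(ang)
          x1 <- x0 + 0.5 * len_px * cos(ang)
          y2 <- y1 + 0.5 * len_px * sin(bend)
          x2 <- x1 + 0.5 * len_px * cos(bend)
          pad <- config$neurite_width_px
          if (min(y0, y1, y2) < 1 + pad || max(y0, y1, y2) > nr - pad ||
            min(x0, x1, x2) < 1 + pad || max(x0, x1, x2) > nc - pad) {
            next
          }
          # keep clear of every other soma
          tt <- seq(0, 1, length.out = 50)
          path <- rbind(
            cbind(y0 + tt * (y1 - y0), x0 + tt * (x1 - x0)),
            cbind(y1 + tt * (y2 - y1), x1 + tt * (x2 - x1))
          )
          clear <- TRUE
          for (j in seq_len(n)) {
            if (j == i) next
            d2 <- (path[, 1] - centers[j, 1])^2 + (path[, 2] - centers[j, 2])^2
            if (any(d2 < (soma_r[j] + config$neurite_width_px)^2)) {
              clear <- FALSE
              break
            }
          }
          if (!clear) next
          px <- rbind(
            segment_pixels(y0, x0, y1, x1, config$neurite_width_px, nr, nc),
            segment_pixels(y1, x1, y2, x2, config$neurite_width_px, nr, nc)
          )
          ch$tubb3[px] <- pmax(ch$tubb3[px], config$marker_intensity)
          neur_len_total <- neur_len_total + len_px * ps
          n_drawn <- n_drawn + 1L
          centreline[[length(centreline) + 1L]] <- path
          drawn <- TRUE
          break
        }
        if (!drawn) {
          rlang::warn("skipping a neurite: no clear path found")
        }
      }
    }

    # --- synaptic puncta -------------------------------------------------
    punct_mask <- list(syni = blank() > 1, psd95 = blank() > 1)
    place_puncta <- function(n_punct, channel) {
      if (n_punct == 0L) {
        return(invisible(NULL))
      }
      all_lines <- if (length(centreline)) do.call(rbind, centreline) else NULL
      taken <- punct_mask$syni | punct_mask$psd95
      for (k in seq_len(n_punct)) {
        for (a in seq_len(config$max_attempts)) {
          if (config$puncta_on_neurite) {
            if (is.null(all_lines)) break
            pt <- all_lines[sample(nrow(all_lines), 1L), ]
          } else {
            pt <- c(runif(1, 3, nr - 3), runif(1, 3, nc - 3))
            # keep well away from any Tubb3 signal
            px_probe <- disc_pixels(pt[1], pt[2],
              config$punctum_radius_px + 2, nr, nc
            )
            if (any(ch$tubb3[px_probe] > 0)) next
          }
          px <- disc_pixels(pt[1], pt[2], config$punctum_radius_px, nr, nc)
          if (any(taken[px])) next
          ch[[channel]][px] <<- config$marker_intensity
          punct_mask[[channel]][px] <<- TRUE
          taken[px] <- TRUE
          break
        }
      }
      invisible(NULL)
    }
    place_puncta(config$n_syni, "syni")
    place_puncta(config$n_psd95, "psd95")

    tubb3_fg <- ch$tubb3 > 0
    syni_on <- sum(punct_mask$syni & tubb3_fg) * ps^2
    psd95_on <- sum(punct_mask$psd95 & tubb3_fg) * ps^2
    syni_tot <- sum(punct_mask$syni) * ps^2
    psd95_tot <- sum(punct_mask$psd95) * ps^2

    # --- background + noise ---------------------------------------------
    for (nm in names(ch)) {
      ch[[nm]] <- ch[[nm]] + config$background
      if (config$noise_sd > 0) {
        ch[[nm]] <- pmax(ch[[nm]] + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc), 0)
      }
    }

    cells <- tibble(
      cell = seq_len(n),
      centroid_row = centers[, 1], centroid_col = centers[, 2],
      nucleus_area_um2 = rendered_area_px * ps^2,
      pyknotic = pyk,
      tubb3 = tubb3, map2 = map2, neun = neun,
      cellrox = crox, mcherry = mch
    )
    structure(
      list(
        stack = channel_stack(ch, ps),
        truth = list(
          cells = cells,
          neurite_length_um = neur_len_total,
          n_neurites_drawn = n_drawn,
          syni_area_um2 = syni_tot,
          syni_on_tubb3_um2 = syni_on,
          psd95_area_um2 = psd95_tot,
          psd95_on_tubb3_um2 = psd95_on
        ),
        config = config
      ),
      class = "field_sim"
    )
  })
}
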