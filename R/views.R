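# Visual-similarity control: procedural synthetic views and the five image
# feature dimensions (2-D FFT magnitude/phase, CIELAB L/a/b).

#' Generate procedural synthetic views for trials
#'
#' Renders, for every trial, a small synthetic RGB scene standing in for the
#' view imagined from the start building towards the target: a sky/ground
#' gradient whose hue drifts with the facing direction and building-like
#' rectangles for layout buildings within the field of view, projected by
#' their angular offset from the facing direction and scaled by distance.
#' These synthetic views exercise the visual-feature pipeline; they are not a
#' VR rendering.
#'
#' @param trials Trial tibble (uses `start_id`, `direction_deg`).
#' @param layout The `city_layout`.
#' @param width,height Image size in pixels.
#' @return A list of `height x width x 3` arrays with values in `[0, 1]`.
#' @export
generate_views <- function(trials, layout, width = 64L, height = 48L) {
  b <- layout$buildings
  fov <- 60
  purrr::map(seq_len(nrow(trials)), function(k) {
    s <- trials$start_id[k]
    facing <- trials$direction_deg[k]
    img <- array(0, dim = c(height, width, 3L))
    horizon <- round(height * 0.55)
    skyv <- seq(1, 0.55, length.out = horizon)
    hue <- 0.5 + 0.2 * cos(facing * pi / 180)
    img[1:horizon, , 1] <- skyv * hue
    img[1:horizon, , 2] <- skyv * 0.8
    img[1:horizon, , 3] <- skyv
    img[(horizon + 1):height, , 1] <- 0.35
    img[(horizon + 1):height, , 2] <- 0.45
    img[(horizon + 1):height, , 3] <- 0.25
    dx <- b$x - b$x[s]; dy <- b$y - b$y[s]
    dist <- sqrt(dx^2 + dy^2)
    ang <- wrap_deg(atan2(dy, dx) * 180 / pi)
    rel <- ((ang - facing + 180) %% 360) - 180
    vis <- which(abs(rel) < fov / 2 & dist > 1e-9)
    for (v in vis[order(-dist[vis])]) {
      cx <- round((rel[v] / fov + 0.5) * (width - 1)) + 1L
      h <- max(3L, round(height * 0.5 / dist[v]))
      w <- max(2L, round(width * 0.2 / dist[v]))
      rows <- max(1L, horizon - h):horizon
      cols <- max(1L, cx - w %/% 2):min(width, cx + w %/% 2)
      shade <- 0.4 + 0.5 * (b$id[v] %% 7) / 7
      img[rows, cols, 1] <- shade
      img[rows, cols, 2] <- shade * 0.9
      img[rows, cols, 3] <- shade * 0.8
    }
    img
  })
}

#' Extract the five visual feature vectors of an image
#'
#' The 2-D discrete Fourier transform of the luminance channel provides
#' magnitude and phase vectors; conversion of the RGB values to CIELAB (D65
#' reference white) provides the L, a and b channel vectors. Each statistic
#' is vectorized for pairwise correlation.
#'
#' @param image A `height x width x 3` RGB array in `[0, 1]`.
#' @return A named list of five numeric vectors: `fft_magnitude`,
#'   `fft_phase`, `L`, `a`, `b`.
#' @export
image_features <- function(image) {
  lum <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  ft <- fft(lum)
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(
    fft_magnitude = as.vector(Mod(ft)),
    fft_phase = as.vector(Arg(ft)),
    L = lab[, 1], a = lab[, 2], b = lab[, 3]
  )
}

#' Pairwise visual similarity per feature dimension
#'
#' Pearson correlation (and Fisher z) between every pair of images, computed
#' separately for each of the five feature dimensions. Dimensions that are
#' constant within an image (e.g. the a/b channels of a grayscale image) are
#' flagged undefined for the affected pairs.
#'
#' @param images List of RGB arrays with equal dimensions.
#' @return A tibble: `i`, `j`, `dimension`, `r`, `z`, `valid`.
#' @export
image_feature_similarity <- function(images) {
  dims <- purrr::map(images, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1L) {
    abort("all images must share the same dimensions.")
  }
  feats <- purrr::map(images, image_features)
  n <- length(images)
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  purrr::map_dfr(names(feats[[1]]), function(dm) {
    fm <- vapply(feats, function(f) f[[dm]], feats[[1]][[dm]])
    sds <- apply(fm, 2L, sd)
    cmat <- suppressWarnings(cor(fm))
    r <- cmat[idx]
    valid <- sds[idx[, 1]] > 0 & sds[idx[, 2]] > 0 & !is.na(r)
    tibble(i = idx[, 1], j = idx[, 2], dimension = dm, r = r,
           z = ifelse(valid, fisher_z(r), NA_real_), valid = valid)
  })
}

#' Test visual-similarity differences between pair groups
#'
#' For each feature dimension, a two-sample t-test compares Fisher-z visual
#' similarity between pairs of trials sampling similar directions (angular
#' difference at most 30 degrees, from different start positions) and pairs
#' sampling dissimilar directions, with Bonferroni correction (default count
#' 24). Dimensions significantly *lower* for similar pairs argue against a
#' visual account of directional pattern-similarity effects.
#'
#' @param feature_sims Tibble from [image_feature_similarity()] for the
#'   trial-wise images.
#' @param labels Pair labels from [label_pairs()] for the same trials.
#' @param n_comparisons Bonferroni correction count (default 24).
#' @return A tibble per dimension: `dimension`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `lower_for_similar`, `significant`.
#' @export
visual_similarity_tests <- function(feature_sims, labels, n_comparisons = 24) {
  key <- paste(labels$i, labels$j)
  similar <- stats::setNames(labels$delta_deg <= 30 & !labels$same_start, key)
  dissimilar <- stats::setNames(labels$delta_deg >= 60 & !labels$same_start, key)
  feature_sims |>
    mutate(key = paste(.data$i, .data$j)) |>
    filter(.data$valid) |>
    group_by(.data$dimension) |>
    dplyr::group_modify(function(df, grp) {
      zs <- df$z[similar[df$key]]
      zd <- df$z[dissimilar[df$key]]
      if (!length(zs) || !length(zd)) abort("empty pair group.")
      if (sd(c(zs, zd)) == 0) {
        return(tibble(statistic = 0, df = length(zs) + length(zd) - 2,
                      p_value = 1, p_adjusted = 1,
                      lower_for_similar = FALSE, significant = FALSE))
      }
      tt <- t.test(zs, zd, var.equal = TRUE)
      padj <- min(1, tt$p.value * n_comparisons)
      tibble(statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             p_adjusted = padj,
             lower_for_similar = mean(zs) < mean(zd),
             significant = padj < 0.05)
    }) |>
    ungroup()
}
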