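#' Seed quality classes
#'
#' The three quality classes of a cereal seed lot as used in sowing quality
#' control: full-value kernels ("select"), undersized kernels
#' ("screenings"), and husk/fragment contaminants ("chaff").
#'
#' @return Character vector of the three class labels, in canonical order.
#' @export
seed_classes <- function() c("select", "screenings", "chaff")

assert_seed_class <- function(label) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% seed_classes())) {
    stop("seed class must be one of: ",
         paste(seed_classes(), collapse = ", "), call. = FALSE)
  }
  label
}

#' Sowing density from mass dose, germination and thousand-kernel weight
#'
#' Converts a mass-based seeding rate to the expected number of germinating
#' seeds per square metre:
#' \deqn{density = rate \cdot 100 \cdot germination / TKW}
#' where `rate` is in kg/ha (1 kg/ha = 0.1 g/m^2), `germination` is the
#' germination capacity as a fraction, and `TKW` is the thousand-kernel
#' weight in grams (1000/TKW seeds per gram). A common triticale dose of
#' 168 kg/ha with TKW 42 g and full germination gives 400 seeds/m^2.
#'
#' @param seed_rate mass dose sown, kg/ha (> 0).
#' @param germination germination capacity, fraction in (0, 1].
#' @param tkw thousand-kernel weight, grams (> 0).
#' @return Seeds per square metre (numeric scalar).
#' @examples
#' sowing_density(168, 1, 42)   # 400 seeds/m^2
#' @export
sowing_density <- function(seed_rate, germination, tkw) {
  if (!is.numeric(seed_rate) || length(seed_rate) != 1L || seed_rate <= 0) {
    stop("seed_rate must be a positive scalar (kg/ha)", call. = FALSE)
  }
  if (!is.numeric(tkw) || length(tkw) != 1L || tkw <= 0) {
    stop("tkw must be a positive scalar (g)", call. = FALSE)
  }
  if (!is.numeric(germination) || length(germination) != 1L ||
      germination <= 0 || germination > 1) {
    stop("germination must be in (0, 1]", call. = FALSE)
  }
  seed_rate * 100 * germination / tkw
}

#' Frame specification for the synthetic seed-flow generator
#'
#' @param width,height frame size in pixels (>= 32 each); defaults match the
#'   640 x 360 video frames of a high-speed seed-flow camera.
#' @param speed airstream transport speed in m/s (> 0); the study speeds are
#'   15, 20 and 25, but any positive value is accepted. Faster transport
#'   produces longer motion blur and hence poorer image quality.
#' @param seed_count number of seeds rendered per frame (>= 0).
#' @param seed_class one of [seed_classes()].
#' @param rng_seed integer seed; frames are bit-identical for equal specs.
#' @return A `frame_spec` list.
#' @export
frame_spec <- function(width = 640L, height = 360L, speed = 15,
                       seed_count = 12L, seed_class = "select",
                       rng_seed = 1L) {
  if (width < 32 || height < 32) {
    stop("frame width and height must be >= 32", call. = FALSE)
  }
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0) {
    stop("speed must be a positive scalar (m/s)", call. = FALSE)
  }
  if (seed_count < 0) stop("seed_count must be >= 0", call. = FALSE)
  assert_seed_class(seed_class)
  structure(list(width = as.integer(width), height = as.integer(height),
                 speed = speed, seed_count = as.integer(seed_count),
                 seed_class = seed_class, rng_seed = as.integer(rng_seed)),
            class = "frame_spec")
}

#' Generator parameters
#'
#' Morphology, contrast and degradation parameters of the synthetic
#' seed-flow imagery. Seeds are photographed dark against a back-lit screen;
#' per class they differ in size, interior granularity and contrast:
#' select kernels are large textured ellipses, screenings are ellipses at
#' roughly half the linear scale, chaff is thin irregular low-contrast
#' fragments. Motion blur is horizontal (the flow direction) with kernel
#' length `round(blur_k * speed)` pixels, so image sharpness degrades
#' monotonically with transport speed.
#'
#' @param bg_level background screen intensity (8-bit).
#' @param tick_pitch pixel pitch of the dark scale ticks on the screen.
#' @param tick_level intensity of the scale ticks.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   applied last (8-bit units), at the reference speed of 15 m/s.
#' @param noise_speed_exp exponent coupling the noise level to transport
#'   speed: the applied noise sd is `noise_sd * (speed / 15)^noise_speed_exp`.
#'   Capturing seeds moving faster under fixed frame pacing, exposure and
#'   bit-rate yields noisier frames, so sensor/compression noise grows with
#'   speed; together with the motion blur this is what degrades image
#'   quality — and hence class separability — at 20 and 25 m/s.
#' @param blur_k motion-blur length per unit speed (px s/m); blur length is
#'   `max(1, round(blur_k * speed))` pixels.
#' @param select,screenings,chaff per-class lists with elements
#'   `axis` (semi-major-axis range, px), `ratio` (minor/major ratio range or
#'   thinness range for chaff), `level` (interior intensity), `tex_sd`
#'   (interior granularity sd).
#' @return A named list of generator parameters.
#' @export
generator_params <- function(bg_level = 200, tick_pitch = 40L,
                             tick_level = 170, noise_sd = 1.0,
                             noise_speed_exp = 2, blur_k = 0.4,
                             select = list(axis = c(14, 18),
                                           ratio = c(0.55, 0.70),
                                           level = 110, tex_sd = 40),
                             screenings = list(axis = c(5.5, 7.5),
                                               ratio = c(0.55, 0.70),
                                               level = 135, tex_sd = 25),
                             chaff = list(axis = c(10, 15),
                                          ratio = c(0.15, 0.28),
                                          level = 184, tex_sd = 6)) {
  list(bg_level = bg_level, tick_pitch = as.integer(tick_pitch),
       tick_level = tick_level, noise_sd = noise_sd,
       noise_speed_exp = noise_speed_exp, blur_k = blur_k,
       select = select, screenings = screenings, chaff = chaff)
}

# Horizontal moving-average blur with replicate edge padding.
blur_horizontal <- function(m, len) {
  len <- as.integer(len)
  if (len <= 1L) return(m)
  w <- ncol(m)
  offsets <- seq_len(len) - 1L - (len - 1L) %/% 2L
  acc <- matrix(0, nrow(m), w)
  for (k in offsets) {
    idx <- pmin(pmax(seq_len(w) + k, 1L), w)
    acc <- acc + m[, idx, drop = FALSE]
  }
  acc / len
}

# Point-in-polygon (crossing number), vectorised over a pixel grid.
polygon_mask <- function(X, Y, vx, vy) {
  n <- length(vx)
  inside <- matrix(FALSE, nrow(X), ncol(X))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > Y) != (vy[j] > Y)) &
      (X < (vx[j] - vx[i]) * (Y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Render one seed into the signed delta layer; returns truth record.
render_seed <- function(delta, spec, params, seed_id) {
  cls <- params[[spec$seed_class]]
  region <- default_crop_region(spec$width, spec$height)
  cx <- runif(1, region$x0, region$x0 + region$w - 1)
  cy <- runif(1, region$y0, region$y0 + region$h - 1)
  a <- runif(1, cls$axis[1], cls$axis[2])
  phi <- runif(1, 0, pi)
  r <- ceiling(a) + 2L
  xs <- max(0L, floor(cx - r)):min(spec$width - 1L, ceiling(cx + r))
  ys <- max(0L, floor(cy - r)):min(spec$height - 1L, ceiling(cy + r))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, length(ys), length(xs)) - cy
  if (spec$seed_class == "chaff") {
    nv <- 7L
    th <- sort(runif(nv, 0, 2 * pi))
    rad <- a * runif(nv, 0.6, 1.0)
    thin <- runif(1, cls$ratio[1], cls$ratio[2])
    px0 <- rad * cos(th)
    py0 <- thin * rad * sin(th)
    vx <- px0 * cos(phi) - py0 * sin(phi)
    vy <- px0 * sin(phi) + py0 * cos(phi)
    mask <- polygon_mask(X, Y, vx, vy)
  } else {
    b <- a * runif(1, cls$ratio[1], cls$ratio[2])
    U <- X * cos(phi) + Y * sin(phi)
    V <- -X * sin(phi) + Y * cos(phi)
    mask <- (U / a)^2 + (V / b)^2 <= 1
  }
  n_in <- sum(mask)
  if (n_in > 0L) {
    interior <- pmin(pmax(cls$level + rnorm(n_in, 0, cls$tex_sd), 0), 255)
    sub <- delta[ys + 1L, xs + 1L, drop = FALSE]
    sub[mask] <- interior - params$bg_level
    delta[ys + 1L, xs + 1L] <- sub
  }
  list(delta = delta,
       truth = data.frame(seed_id = seed_id, cx = cx, cy = cy,
                          area_px = n_in))
}

#' Generate one synthetic seed-flow frame
#'
#' Renders `spec$seed_count` seeds of one class on a back-lit screen with
#' scale ticks, applies horizontal motion blur whose length grows with the
#' transport speed, then additive Gaussian noise. Deterministic for a fixed
#' `rng_seed`. Seeds whose geometry extends beyond the frame are clipped.
#'
#' @param spec a [frame_spec()].
#' @param params a [generator_params()] list.
#' @return list with `image` (a [gray_image()]) and `truth` (data.frame with
#'   columns seed_id, cx, cy, area_px; 0-based pixel coordinates, origin
#'   top-left; empty when `seed_count` is 0).
#' @export
generate_seed_frame <- function(spec, params = generator_params()) {
  stopifnot(inherits(spec, "frame_spec"))
  with_rng(spec$rng_seed, {
    bg <- matrix(params$bg_level, spec$height, spec$width)
    ticks <- seq(params$tick_pitch, spec$width - 1L, by = params$tick_pitch)
    bg[, ticks] <- params$tick_level
    delta <- matrix(0, spec$height, spec$width)
    truth <- vector("list", spec$seed_count)
    for (i in seq_len(spec$seed_count)) {
      res <- render_seed(delta, spec, params, i)
      delta <- res$delta
      truth[[i]] <- res$truth
    }
    blur_len <- max(1L, as.integer(round(params$blur_k * spec$speed)))
    out <- bg + blur_horizontal(delta, blur_len)
    sigma <- params$noise_sd * (spec$speed / 15)^params$noise_speed_exp
    out <- out + rnorm(length(out), 0, sigma)
    out <- pmin(pmax(round(out), 0), 255)
    truth_df <- if (spec$seed_count > 0L) do.call(rbind, truth) else
      data.frame(seed_id = integer(), cx = numeric(), cy = numeric(),
                 area_px = integer())
    list(image = gray_image(out), truth = truth_df)
  })
}

#' Generate a labelled synthetic dataset of seed-flow frames
#'
#' @param counts data.frame with columns `speed`, `class`, `n_frames`: the
#'   number of frames to generate for each (speed, class) cell. The study
#'   design used balanced cells, e.g. 200 frames per class at 15 m/s.
#' @param rng_seed master seed; per-frame seeds are derived from it, so the
#'   whole dataset is reproducible.
#' @param params a [generator_params()] list.
#' @param seed_count seeds rendered per frame.
#' @param width,height frame size.
#' @return A list with one element per frame, each a list with `image`,
#'   `truth`, `class` and `speed`. Length equals `sum(counts$n_frames)`;
#'   per-cell counts are honoured exactly.
#' @export
generate_dataset <- function(counts, rng_seed, params = generator_params(),
                             seed_count = 12L, width = 640L, height = 360L) {
  if (!is.data.frame(counts) ||
      !all(c("speed", "class", "n_frames") %in% names(counts))) {
    stop("counts must have columns speed, class, n_frames", call. = FALSE)
  }
  if (nrow(counts) == 0L) return(list())
  if (any(counts$n_frames < 0)) stop("n_frames must be >= 0", call. = FALSE)
  for (cl in counts$class) assert_seed_class(cl)
  total <- sum(counts$n_frames)
  if (total == 0L) return(list())
  seeds <- derive_seeds(rng_seed, total)
  out <- vector("list", total)
  k <- 0L
  for (r in seq_len(nrow(counts))) {
    for (i in seq_len(counts$n_frames[r])) {
      k <- k + 1L
      spec <- frame_spec(width = width, height = height,
                         speed = counts$speed[r], seed_count = seed_count,
                         seed_class = counts$class[r], rng_seed = seeds[k])
      fr <- generate_seed_frame(spec, params)
      out[[k]] <- list(image = fr$image, truth = fr$truth,
                       class = counts$class[r], speed = counts$speed[r])
    }
  }
  out
}

#' Frame counts for the study's training-set designs
#'
#' The four balanced designs: Z1 = 200 frames/class at 15 m/s (600 cases),
#' Z2 = 50/class at 20 m/s (150), Z3 = 100/class at 25 m/s (300), Z4 =
#' 200/class at each of 15, 20, 25 m/s (1800).
#'
#' @param name one of "Z1", "Z2", "Z3", "Z4".
#' @return counts data.frame suitable for [generate_dataset()].
#' @export
set_design <- function(name) {
  name <- match.arg(name, c("Z1", "Z2", "Z3", "Z4"))
  grid <- switch(name,
    Z1 = expand.grid(speed = 15, class = seed_classes(), n = 200),
    Z2 = expand.grid(speed = 20, class = seed_classes(), n = 50),
    Z3 = expand.grid(speed = 25, class = seed_classes(), n = 100),
    Z4 = expand.grid(speed = c(15, 20, 25), class = seed_classes(), n = 200)
  )
  data.frame(speed = grid$speed, class = as.character(grid$class),
             n_frames = grid$n)
}

#' Write a generated dataset to disk
#'
#' Frames are written as 8-bit PNG, ground truth as one CSV with columns
#' frame_path, class, speed_mps, seed_id, cx, cy, area_px.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return Path of the ground-truth CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    entry <- dataset[[i]]
    fname <- sprintf("frame_%05d_%s_%g.png", i, entry$class, entry$speed)
    write_image(entry$image, file.path(dir, fname))
    tr <- entry$truth
    rows[[i]] <- if (nrow(tr) > 0L) {
      data.frame(frame_path = fname, class = entry$class,
                 speed_mps = entry$speed, tr)
    } else NULL
  }
  csv <- file.path(dir, "ground_truth.csv")
  write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
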