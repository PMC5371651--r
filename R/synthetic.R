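#' Evaluate code with a local, restored random seed
#'
#' All synthetic-data randomness flows through this helper so a fixed seed
#' gives bit-identical datasets without touching the caller's random
#' state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Canonical procedural glyph shapes, painted as binary ink on an s x s
# canvas.  Shapes are chosen to be pairwise dissimilar (ZMNCC < 0.8).
glyph_shape <- function(class_id, size) {
  R <- matrix(seq_len(size), size, size)
  C <- matrix(seq_len(size), size, size, byrow = TRUE)
  ctr <- (size + 1) / 2
  R <- (R - ctr) / (size / 2)
  C <- (C - ctr) / (size / 2)
  t <- 0.13
  ink <- switch(as.integer(class_id),
    (abs(R) < t & abs(C) < 0.7) | (abs(C) < t & abs(R) < 0.7),          # plus
    (abs(R - C) < 1.4 * t | abs(R + C) < 1.4 * t) &
      abs(R) < 0.7 & abs(C) < 0.7,                                      # X
    pmax(abs(R), abs(C)) > 0.48 & pmax(abs(R), abs(C)) < 0.48 + 2 * t,  # square
    {
      d <- sqrt(R^2 + C^2)
      d > 0.45 & d < 0.45 + 2 * t                                       # circle
    },
    (abs(R + 0.55) < t & abs(C) < 0.65) |
      (abs(C) < t & R > -0.55 & R < 0.65),                              # T
    (abs(C + 0.55) < t & R > -0.65 & R < 0.55) |
      (abs(R - 0.55) < t & abs(C) < 0.65),                              # L
    (abs(R - 0.35) < t | abs(R + 0.35) < t) & abs(C) < 0.65,            # =
    (abs(C - 0.35) < t | abs(C + 0.35) < t) & abs(R) < 0.65,            # ||
    {
      d <- abs(R) + abs(C)
      d > 0.58 & d < 0.58 + 2.4 * t                                     # diamond
    },
    (abs(R + 0.55) < t & abs(C) < 0.6) |
      (abs(R - 0.55) < t & abs(C) < 0.6) |
      (abs(C + R * (0.6 / 0.55)) < 1.5 * t & abs(R) < 0.55)             # Z
  )
  if (is.null(ink)) stop("at most 10 glyph classes are defined")
  ink * 1.0
}

#' Specification of a synthetic multi-class glyph dataset
#'
#' Defines the world the synthetic generator emulates: distinct procedural
#' shapes per class, perturbed per instance by affine jitter, additive
#' Gaussian pixel noise and a random linear illumination gradient.
#'
#' @param n_classes number of classes (2..10); default 10.
#' @param image_size canvas side in pixels (odd keeps the glyph centred on
#'   a pixel); default 25.
#' @param jitter_px maximum |translation| per axis in pixels; default 2.
#' @param jitter_deg maximum |rotation| in degrees; default 8.
#' @param scale_range instance scale factor range; default c(0.9, 1.1).
#' @param noise_sigma additive Gaussian noise std (intensity units);
#'   default 0.05.
#' @param illumination linear gradient amplitude range (peak-to-peak
#'   intensity across the canvas); default c(0, 0.3).
#' @param seed integer seed; fixed seed gives bit-identical datasets.
#' @return object of class `glyph_spec`.
#' @export
glyph_spec <- function(n_classes = 10L, image_size = 25L, jitter_px = 2,
                       jitter_deg = 8, scale_range = c(0.9, 1.1),
                       noise_sigma = 0.05, illumination = c(0, 0.3),
                       seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 glyph classes")
  if (n_classes > 10L) stop("at most 10 glyph classes are defined")
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 jitter_px = jitter_px, jitter_deg = jitter_deg,
                 scale_range = scale_range, noise_sigma = noise_sigma,
                 illumination = illumination, seed = as.integer(seed)),
            class = "glyph_spec")
}

# One perturbed glyph instance (ink in [0, 1] before noise/illumination).
render_glyph_instance <- function(spec, class_id, translate = TRUE) {
  base <- glyph_shape(class_id, spec$image_size)
  ang <- runif(1L, -spec$jitter_deg, spec$jitter_deg)
  sc <- runif(1L, spec$scale_range[1L], spec$scale_range[2L])
  dr <- if (translate) runif(1L, -spec$jitter_px, spec$jitter_px) else 0
  dc <- if (translate) runif(1L, -spec$jitter_px, spec$jitter_px) else 0
  warp_affine(base, ang, sc, dr, dc)
}

add_photometric <- function(img, spec) {
  s <- nrow(img)
  amp <- runif(1L, spec$illumination[1L], spec$illumination[2L])
  phi <- runif(1L, 0, 2 * pi)
  R <- (matrix(seq_len(s), s, ncol(img)) - (s + 1) / 2) / s
  C <- (matrix(seq_len(ncol(img)), s, ncol(img), byrow = TRUE) -
          (ncol(img) + 1) / 2) / ncol(img)
  img <- img + amp * (cos(phi) * R + sin(phi) * C)
  if (spec$noise_sigma > 0) {
    img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                        nrow(img), ncol(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a balanced multi-class glyph dataset
#'
#' Train and test splits are disjoint random draws.  Counts must divide
#' evenly by the number of classes.
#'
#' @param spec a [glyph_spec()].
#' @param n_train,n_test total image counts (balanced across classes).
#' @return list with `train` and `test`, each a list of `images` and
#'   `labels` (labels `"c1"`, `"c2"`, ...), plus `spec`.
#' @export
make_glyph_dataset <- function(spec, n_train, n_test) {
  stopifnot(inherits(spec, "glyph_spec"))
  if (n_train %% spec$n_classes != 0L || n_test %% spec$n_classes != 0L) {
    stop("n_train and n_test must be multiples of n_classes (balanced sets)")
  }
  gen_split <- function(n_per_class) {
    images <- list(); labels <- character(0)
    for (cl in seq_len(spec$n_classes)) {
      for (i in seq_len(n_per_class)) {
        img <- add_photometric(render_glyph_instance(spec, cl), spec)
        images[[length(images) + 1L]] <- img
        labels <- c(labels, paste0("c", cl))
      }
    }
    list(images = images, labels = labels)
  }
  with_seed(spec$seed, {
    train <- gen_split(n_train %/% spec$n_classes)
    test <- gen_split(n_test %/% spec$n_classes)
    list(train = train, test = test, spec = spec)
  })
}

#' Generate registered object crops for detector training
#'
#' Each crop contains one glyph of the target class centred on the crop
#' centre (no translation jitter; rotation/scale jitter and photometric
#' perturbations are applied), over a weak clutter background.
#'
#' @param spec a [glyph_spec()].
#' @param n number of crops.
#' @param class_id target class; default 1.
#' @param clutter background clutter amplitude in `[0, 1]`; default 0.2.
#' @param seed seed; defaults to `spec$seed`.
#' @return list of image matrices of size `image_size` (odd).
#' @export
make_object_crops <- function(spec, n, class_id = 1L, clutter = 0.2,
                              seed = spec$seed) {
  stopifnot(inherits(spec, "glyph_spec"))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ink <- render_glyph_instance(spec, class_id, translate = FALSE)
      bg <- clutter_background(spec$image_size, spec$image_size, clutter)
      add_photometric(pmax(bg, ink), spec)
    })
  })
}

# Textured background: Gaussian-filtered uniform noise, standardized and
# scaled by the clutter density.
clutter_background <- function(h, w, density) {
  if (density <= 0) return(matrix(0.15, h, w))
  z <- gaussian_smooth(matrix(runif(h * w), h, w), 1.5)
  z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
  pmin(pmax(0.2 + 0.1 * density * z, 0), 0.55)
}

#' Specification of synthetic cluttered scenes
#'
#' @param scene_size scene side in pixels; default 64.
#' @param n_objects inclusive range of planted objects per scene; default
#'   c(0, 3).
#' @param clutter background clutter density in `[0, 1]`; default 0.5.
#' @param scale_range planted object scale range; default c(1, 1)
#'   (single-scale scenes).
#' @param seed integer seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(scene_size = 64L, n_objects = c(0L, 3L),
                       clutter = 0.5, scale_range = c(1, 1), seed = 1L) {
  structure(list(scene_size = as.integer(scene_size),
                 n_objects = as.integer(n_objects), clutter = clutter,
                 scale_range = scale_range, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate annotated cluttered scenes containing glyph instances
#'
#' Each scene is a textured-clutter background with between
#' `spec$n_objects[1]` and `spec$n_objects[2]` instances of the target
#' glyph class planted at random positions (and scales), subject to no two
#' objects overlapping by more than 25% of the smaller object's area.
#' Every planted object is annotated with its centre, size and scale.
#' Object-free scenes are also produced for harvesting non-target training
#' patches.
#'
#' @param spec a [scene_spec()].
#' @param glyphs a [glyph_spec()] describing the planted objects.
#' @param n_scenes number of annotated scenes.
#' @param class_id planted glyph class; default 1.
#' @param n_background number of object-free scenes; default `n_scenes`.
#' @return list with `scenes` (list of matrices), `annotations` (data
#'   frame: image, row, col, width, height, scale_index) and `negatives`
#'   (list of object-free matrices).
#' @export
make_scene_dataset <- function(spec, glyphs, n_scenes, class_id = 1L,
                               n_background = n_scenes) {
  stopifnot(inherits(spec, "scene_spec"), inherits(glyphs, "glyph_spec"))
  g <- glyphs$image_size
  if (g * max(spec$scale_range) > spec$scene_size) {
    stop("objects larger than the scene")
  }
  half_max <- ceiling(g * max(spec$scale_range) / 2)
  ann <- list()
  with_seed(spec$seed, {
    scenes <- lapply(seq_len(n_scenes), function(si) {
      sc <- clutter_background(spec$scene_size, spec$scene_size, spec$clutter)
      k <- spec$n_objects[1L] +
        sample.int(spec$n_objects[2L] - spec$n_objects[1L] + 1L, 1L) - 1L
      placed <- matrix(numeric(0), 0L, 3L)  # row, col, half-extent
      for (q in seq_len(k)) {
        osc <- runif(1L, spec$scale_range[1L], spec$scale_range[2L])
        ink <- render_glyph_instance(glyphs, class_id, translate = FALSE)
        if (osc != 1) ink <- resize_bilinear(ink, osc)
        ink <- odd_crop(ink)
        half <- (nrow(ink) - 1L) %/% 2L
        ext <- 0.75 * nrow(ink) / 2  # approx glyph ink half-extent
        pos <- NULL
        for (try in seq_len(50L)) {
          r <- sample((half_max + 1L):(spec$scene_size - half_max), 1L)
          cc <- sample((half_max + 1L):(spec$scene_size - half_max), 1L)
          ok <- TRUE
          if (nrow(placed) > 0L) {
            for (pq in seq_len(nrow(placed))) {
              ov <- box_overlap_frac(c(r, cc, ext), placed[pq, ])
              if (ov > 0.25) { ok <- FALSE; break }
            }
          }
          if (ok) { pos <- c(r, cc); break }
        }
        if (is.null(pos)) next  # scene too crowded; plant fewer objects
        rows <- (pos[1L] - half):(pos[1L] + half)
        cols <- (pos[2L] - half):(pos[2L] + half)
        sc[rows, cols] <- pmax(sc[rows, cols], ink)
        placed <- rbind(placed, c(pos, ext))
        ann[[length(ann) + 1L]] <<- data.frame(
          image = si, row = pos[1L], col = pos[2L],
          width = round(2 * ext), height = round(2 * ext),
          scale_index = 0L)
      }
      add_photometric(sc, glyphs)
    })
    negatives <- lapply(seq_len(n_background), function(i) {
      add_photometric(clutter_background(spec$scene_size, spec$scene_size,
                                         spec$clutter), glyphs)
    })
    annotations <- if (length(ann) == 0L) {
      data.frame(image = integer(0), row = numeric(0), col = numeric(0),
                 width = numeric(0), height = numeric(0),
                 scale_index = numeric(0))
    } else {
      do.call(rbind, ann)
    }
    list(scenes = scenes, annotations = annotations, negatives = negatives)
  })
}

# Overlap between two square boxes (row, col, half-extent) as a fraction
# of the smaller box's area.
box_overlap_frac <- function(a, b) {
  dr <- max(0, min(a[1L] + a[3L], b[1L] + b[3L]) -
              max(a[1L] - a[3L], b[1L] - b[3L]))
  dc <- max(0, min(a[2L] + a[3L], b[2L] + b[3L]) -
              max(a[2L] - a[3L], b[2L] - b[3L]))
  inter <- dr * dc
  inter / min((2 * a[3L])^2, (2 * b[3L])^2)
}
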