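# Synthetic colony sequences with analytic ground truth.
#
# Emulates the appearance of phase-contrast colony images -- textured,
# roughly circular colonies on a darker background, optional bright halo --
# and scripts their dynamics (translation, isotropic growth, merging,
# splitting) so that true masks, true displacement fields and a true event
# log are known exactly. Every other module is validated against these.

#' Scenario script for the sequence generator
#'
#' @param canvas `c(height, width)` in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param colonies List of colony specs, each a list with `id` (positive
#'   integer), `center` (`c(row, col)` at frame 0), `radius` (pixels, >= 3),
#'   optional `velocity` (`c(row, col)` pixels/frame, default 0), `growth`
#'   (relative radius increase per frame, default 0) and `texture_seed`.
#' @param events List of scripted events: `list(frame =, type = "merge",
#'   ids = c(a, b))` pins colony `b` against colony `a` (4 px overlap) from
#'   `frame` on; `list(frame =, type = "split", id =, offsets = list(c(dr,
#'   dc), c(dr, dc)))` replaces colony `id` by two equal-area children
#'   drifting apart with the given relative velocities from `frame` on.
#' @param noise_sigma Gaussian pixel noise added after compositing.
#' @param halo_amplitude Brightness of the halo ring outside each colony
#'   (0 disables).
#' @param seed Integer; fixes all randomness of the generator.
#' @return A `scenario_script` list.
#' @export
scenario_script <- function(canvas = c(160, 160), n_frames = 8,
                            colonies = list(), events = list(),
                            noise_sigma = 0.03, halo_amplitude = 0,
                            seed = 1L) {
  if (n_frames < 2) stopf("a scenario needs >= 2 frames")
  ids <- vapply(colonies, function(cl) as.integer(cl$id), integer(1))
  if (anyDuplicated(ids)) stopf("colony ids must be unique")
  for (ev in events) {
    ref <- if (ev$type == "merge") ev$ids else ev$id
    if (!all(ref %in% ids)) stopf("event references unknown colony id")
    if (ev$frame < 1 || ev$frame >= n_frames) {
      stopf("event frame %d outside 1..%d", ev$frame, n_frames - 1)
    }
  }
  structure(list(canvas = as.integer(canvas), n_frames = as.integer(n_frames),
                 colonies = colonies, events = events,
                 noise_sigma = noise_sigma, halo_amplitude = halo_amplitude,
                 seed = as.integer(seed)),
            class = "scenario_script")
}

# background and interior levels of the synthetic frames: contrast 0.4
# matches the >= 0.3 contrast regime the segmentation suite assumes
.synth_background <- 0.2
.synth_interior <- 0.6

# Band-limited texture patch for one colony, in colony-local coordinates.
# `extent` is the half-size in pixels at reference radius.
colony_texture <- function(extent, texture_seed) {
  n <- 2L * as.integer(ceiling(extent)) + 1L
  with_seed(texture_seed, {
    t0 <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), 1.5)
    clamp(.synth_interior + 0.12 * t0 / stats::sd(t0), 0.35, 0.9)
  })
}

# Draw one colony onto `img`: textured disc, optional halo ring outside the
# mask. The texture is anchored to colony-local coordinates scaled by
# radius/ref_radius, so motion and growth advect it consistently.
draw_colony <- function(img, center, radius, tex, ref_radius, halo_amplitude) {
  h <- nrow(img); w <- ncol(img)
  g <- coord_grid(h, w)
  d <- sqrt((g$r - center[1])^2 + (g$c - center[2])^2)
  inside <- d <= radius
  if (any(inside)) {
    half <- (nrow(tex) - 1) / 2
    scale <- ref_radius / radius
    lr <- (g$r[inside] - center[1]) * scale + half + 1
    lc <- (g$c[inside] - center[2]) * scale + half + 1
    img[inside] <- bilinear_sample(tex, lr, lc)
  }
  if (halo_amplitude > 0) {
    ring <- d > radius & d <= radius + 5
    img[ring] <- clamp(img[ring] +
      halo_amplitude * exp(-((d[ring] - radius)^2) / (2 * 1.5^2)), 0, 1)
  }
  list(img = img, inside = inside)
}

#' Render a single textured colony
#'
#' One textured disc with optional halo on a uniform background, plus its
#' exact rasterized mask. Deterministic in `texture_seed`.
#'
#' @param center `c(row, col)` center.
#' @param radius Disc radius in pixels (>= 3).
#' @param texture_seed Integer seed for the interior texture.
#' @param halo_amplitude Halo ring brightness (0 disables).
#' @param canvas `c(height, width)`.
#' @return List with `image` (matrix in `[0, 1]`) and `mask` (0/1 integer
#'   matrix).
#' @export
make_textured_colony <- function(center, radius, texture_seed = 1L,
                                 halo_amplitude = 0, canvas = c(128, 128)) {
  if (radius < 3) stopf("radius must be >= 3 px")
  img <- matrix(.synth_background, canvas[1], canvas[2])
  tex <- colony_texture(radius + 4, texture_seed)
  dr <- draw_colony(img, center, radius, tex, radius, halo_amplitude)
  list(image = dr$img, mask = matrix(as.integer(dr$inside), canvas[1], canvas[2]))
}

#' Closed-form displacement fields
#'
#' Analytic ground-truth fields for registration tests: `"translation"`
#' (constant vector), `"rotation"` (rigid rotation about `center` by angle
#' `magnitude`, radians) and `"radial_growth"` (`u(x) = s * (x - center)`
#' with `s = magnitude`), optionally tapered to zero outside
#' `support_radius` over `taper_width` pixels.
#'
#' @param kind One of `"translation"`, `"rotation"`, `"radial_growth"`.
#' @param magnitude Translation vector `c(dr, dc)`, rotation angle, or
#'   radial strain, respectively.
#' @param center `c(row, col)` center for rotation/growth.
#' @param dim `c(height, width)` of the field.
#' @param support_radius Radius within which the field is at full strength.
#' @param taper_width Width of the linear taper band outside
#'   `support_radius`.
#' @return `h x w x 2` displacement array.
#' @export
analytic_field <- function(kind = c("translation", "rotation", "radial_growth"),
                           magnitude, center = NULL, dim = c(128, 128),
                           support_radius = Inf, taper_width = 0) {
  kind <- match.arg(kind)
  h <- dim[1]; w <- dim[2]
  u <- array(0, c(h, w, 2))
  g <- coord_grid(h, w)
  if (kind == "translation") {
    if (length(magnitude) == 1) magnitude <- c(magnitude, 0)
    u[, , 1] <- magnitude[1]
    u[, , 2] <- magnitude[2]
  } else {
    if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
    dr <- g$r - center[1]; dc <- g$c - center[2]
    if (kind == "rotation") {
      th <- magnitude
      # content rotated by th about center: u = (I - R(-th)) (x - c)
      u[, , 1] <- dr - (cos(th) * dr + sin(th) * dc)
      u[, , 2] <- dc - (-sin(th) * dr + cos(th) * dc)
    } else {
      u[, , 1] <- magnitude * dr
      u[, , 2] <- magnitude * dc
    }
  }
  if (is.finite(support_radius)) {
    d <- sqrt((g$r - center[1])^2 + (g$c - center[2])^2)
    wgt <- clamp((support_radius + taper_width - d) / max(taper_width, 1e-9), 0, 1)
    wgt[d <= support_radius] <- 1
    u[, , 1] <- u[, , 1] * wgt
    u[, , 2] <- u[, , 2] * wgt
  }
  u
}

# Per-frame colony states (center, radius, parent) after applying the script
# events. Returns a list indexed by frame (1-based) of tibbles.
scenario_states <- function(script) {
  n <- script$n_frames
  base <- lapply(script$colonies, function(cl) {
    list(id = as.integer(cl$id),
         center = as.numeric(cl$center),
         radius = as.numeric(cl$radius),
         velocity = as.numeric(cl$velocity %||% c(0, 0)),
         growth = as.numeric(cl$growth %||% 0),
         texture_seed = as.integer(cl$texture_seed %||% (script$seed + cl$id)))
  })
  names(base) <- vapply(base, function(b) as.character(b$id), character(1))
  next_id <- max(vapply(base, function(b) b$id, integer(1))) + 1L

  states <- vector("list", n)
  events_log <- list()
  # active colony records: id, center, radius, velocity, growth, seed,
  # ref_radius (texture anchor), parent
  active <- lapply(base, function(b) {
    c(b, list(ref_radius = b$radius, parent = NA_integer_))
  })
  merged_pair <- list()  # id -> id it is pinned to

  for (t in seq_len(n)) {
    frame0 <- t - 1L
    for (ev in script$events) {
      if (ev$frame != frame0) next
      if (ev$type == "merge") {
        a <- as.character(ev$ids[1]); b <- as.character(ev$ids[2])
        merged_pair[[b]] <- a
        events_log[[length(events_log) + 1]] <- tibble::tibble(
          frame = frame0, type = "merge",
          ids = paste(ev$ids, collapse = "+"))
      } else if (ev$type == "split") {
        pid <- as.character(ev$id)
        parent <- active[[pid]]
        if (is.null(parent)) stopf("split of inactive colony %s", pid)
        r_child <- parent$radius / sqrt(2)
        kids <- integer(0)
        for (k in seq_along(ev$offsets)) {
          kid <- next_id; next_id <- next_id + 1L
          off <- as.numeric(ev$offsets[[k]])
          len <- sqrt(sum(off^2))
          unit <- if (len < 1e-9) c(0, (-1)^k) else off / len
          active[[as.character(kid)]] <- list(
            id = kid,
            # children start just-separated along their offset direction, so
            # the scripted frame is the frame the topology visibly changes
            center = parent$center + unit * (r_child + 2.5),
            radius = r_child,
            velocity = parent$velocity + off,
            growth = parent$growth,
            texture_seed = parent$texture_seed + k,
            ref_radius = r_child, parent = parent$id)
          kids <- c(kids, kid)
        }
        active[[pid]] <- NULL
        events_log[[length(events_log) + 1]] <- tibble::tibble(
          frame = frame0, type = "split",
          ids = paste(c(parent$id, kids), collapse = "+"))
      }
    }
    # pin merged colonies to 4 px overlap against their partner (from the
    # event frame on, so the scripted contact frame is exact)
    for (b in names(merged_pair)) {
      a <- merged_pair[[b]]
      if (is.null(active[[a]]) || is.null(active[[b]])) next
      dir <- active[[b]]$center - active[[a]]$center
      len <- sqrt(sum(dir^2))
      dir <- if (len < 1e-9) c(0, 1) else dir / len
      gap <- active[[a]]$radius + active[[b]]$radius - 4
      active[[b]]$center <- active[[a]]$center + dir * gap
    }
    states[[t]] <- active
    # advance to next frame
    active <- lapply(active, function(cl) {
      cl$center <- cl$center + cl$velocity
      cl$radius <- cl$radius * (1 + cl$growth)
      cl
    })
  }
  ev_tbl <- if (length(events_log) == 0) {
    tibble::tibble(frame = integer(), type = character(), ids = character())
  } else {
    dplyr::bind_rows(events_log)
  }
  list(states = states, events = ev_tbl)
}

# truth label mask for one frame's colony states: pixels in several discs go
# to the colony with the smallest radius-normalized center distance
truth_mask <- function(states_t, canvas) {
  h <- canvas[1]; w <- canvas[2]
  mask <- matrix(0L, h, w)
  if (length(states_t) == 0) return(mask)
  g <- coord_grid(h, w)
  best <- matrix(Inf, h, w)
  ord <- order(vapply(states_t, function(cl) cl$id, integer(1)))
  for (cl in states_t[ord]) {
    d <- sqrt((g$r - cl$center[1])^2 + (g$c - cl$center[2])^2)
    sel <- d <= cl$radius & (d / cl$radius) < best
    mask[sel] <- cl$id
    best[sel] <- (d / cl$radius)[sel]
  }
  mask
}

# ground-truth field mapping frame t onto t+1 (indices 1-based states)
truth_field <- function(st_now, st_next, canvas, taper = 6) {
  h <- canvas[1]; w <- canvas[2]
  u <- array(0, c(h, w, 2))
  if (length(st_next) == 0) return(u)
  g <- coord_grid(h, w)
  best <- matrix(Inf, h, w)
  for (cl in st_next) {
    src <- st_now[[as.character(cl$id)]]
    if (is.null(src) && !is.na(cl$parent)) {
      src <- st_now[[as.character(cl$parent)]]
    }
    if (is.null(src)) next
    d <- sqrt((g$r - cl$center[1])^2 + (g$c - cl$center[2])^2)
    sel <- d <= cl$radius + taper & d < best
    if (!any(sel)) next
    s <- 1 - src$radius / cl$radius
    wgt <- clamp((cl$radius + taper - d[sel]) / taper, 0, 1)
    shift <- cl$center - src$center
    u1 <- (shift[1] + s * (g$r[sel] - cl$center[1])) * wgt
    u2 <- (shift[2] + s * (g$c[sel] - cl$center[2])) * wgt
    u[, , 1][sel] <- u1
    u[, , 2][sel] <- u2
    best[sel] <- d[sel]
  }
  u
}

#' Generate a synthetic colony sequence with ground truth
#'
#' Composites textured colonies per the scenario script (translation, growth,
#' scripted merges and splits), adds seeded Gaussian noise, and records the
#' exact truth: per-frame label masks, per-pair analytic displacement fields,
#' and the event log. Bit-reproducible from the script's seed.
#'
#' @param script A [scenario_script()].
#' @return List with `frames` (list of frame objects), `truth` (list with
#'   `masks`, `fields`, `events`), and `script`.
#' @export
generate_sequence <- function(script) {
  stopifnot(inherits(script, "scenario_script"))
  sc <- scenario_states(script)
  n <- script$n_frames
  canvas <- script$canvas
  h <- canvas[1]; w <- canvas[2]

  # texture patches per colony lineage (children have their own seeds)
  tex <- list()
  ref_radius <- list()
  for (t in seq_len(n)) {
    for (cl in sc$states[[t]]) {
      key <- as.character(cl$id)
      if (is.null(tex[[key]])) {
        tex[[key]] <- colony_texture(cl$ref_radius * 1.6 + 4, cl$texture_seed)
        ref_radius[[key]] <- cl$ref_radius
      }
    }
  }

  frames <- vector("list", n)
  masks <- vector("list", n)
  clipped <- FALSE
  for (t in seq_len(n)) {
    img <- matrix(.synth_background, h, w)
    ord <- order(vapply(sc$states[[t]], function(cl) cl$id, integer(1)))
    for (cl in sc$states[[t]][ord]) {
      key <- as.character(cl$id)
      if (any(cl$center - cl$radius < 1) || cl$center[1] + cl$radius > h ||
          cl$center[2] + cl$radius > w) clipped <- TRUE
      dr <- draw_colony(img, cl$center, cl$radius, tex[[key]],
                        ref_radius[[key]], script$halo_amplitude)
      img <- dr$img
    }
    if (script$noise_sigma > 0) {
      img <- with_seed(script$seed + 7919L * t, {
        clamp(img + matrix(stats::rnorm(h * w, 0, script$noise_sigma), h, w), 0, 1)
      })
    }
    frames[[t]] <- new_frame(img, t - 1L)
    masks[[t]] <- truth_mask(sc$states[[t]], canvas)
  }
  if (clipped) warning("colony extends beyond the canvas; clipped", call. = FALSE)

  fields <- vector("list", n - 1)
  for (t in seq_len(n - 1)) {
    fields[[t]] <- truth_field(sc$states[[t]], sc$states[[t + 1]], canvas)
  }
  list(frames = frames,
       truth = list(masks = masks, fields = fields, events = sc$events),
       script = script)
}
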