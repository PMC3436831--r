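# Colony tracking by displacement-driven label propagation.
#
# Per frame pair: register -> propagate the previous label mask with the
# displacement field -> segment the new frame (initialized by the propagated
# mask) -> reconcile propagated and segmented objects into a consistent
# labeling, classifying each correspondence as one-to-one, merge, split or
# newly appearing. Backward tracking processes the reversed sequence, which
# turns forward-time merges into splits (segmentations delineate separating
# objects more reliably than fusing ones).

#' Tracking parameters
#'
#' @param min_overlap_px Minimum shared pixels for a propagated/segmented
#'   correspondence to count (suppresses 1-px warping slivers).
#' @param direction `"forward"` or `"backward"` processing order. Backward is
#'   the default: object splitting (which segmentation handles well) then
#'   stands in for forward-time merging.
#' @param registration A [registration_params()] list. The tracking default
#'   differs from the standalone registration default: a stronger curvature
#'   weight (`alpha = 3`) keeps the field smooth and topology-preserving
#'   when colonies deform, merge or split (a floppy field can collapse a
#'   propagated mask onto one subcolony), and a relaxed stopping tolerance
#'   and step budget suffice because label propagation only needs the coarse
#'   inter-frame motion -- the per-frame segmentation refines mask shapes.
#' @param segmentation A [segmentation_params()] list.
#' @param max_displacement_px Plausibility bound on the recovered field
#'   (pixels). Inter-frame colony motion sits well below 8 px in the imaging
#'   regime this pipeline targets; a field exceeding the bound indicates the
#'   registration ran away (typically while trying to follow a topology
#'   change) and is replaced by the identity field with a warning, so the
#'   overlap-based reconciliation sees the undeformed mask instead of a
#'   collapsed one.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(min_overlap_px = 10L,
                            direction = c("backward", "forward"),
                            registration = registration_params(
                              alpha = 3, convergence_rel_change = 3e-3,
                              max_steps = 120L),
                            segmentation = segmentation_params(),
                            max_displacement_px = 12) {
  direction <- match.arg(direction)
  if (min_overlap_px < 1) stopf("min_overlap_px must be >= 1")
  if (max_displacement_px <= 0) stopf("max_displacement_px must be > 0")
  structure(list(min_overlap_px = as.integer(min_overlap_px),
                 direction = direction,
                 registration = registration,
                 segmentation = segmentation,
                 max_displacement_px = max_displacement_px),
            class = "tracking_params")
}

#' Propagate a label mask along a displacement field
#'
#' Warps the mask with nearest-neighbour sampling at `x - u(x)`, so label
#' values are preserved exactly (no interpolated labels are invented). The
#' warped support of one label may become non-contiguous.
#'
#' @param mask Integer label matrix at time `t`.
#' @param field Displacement field registering frame `t` onto frame `t + 1`.
#' @return Integer label matrix estimating label positions at `t + 1`.
#' @export
propagate_labels <- function(mask, field) {
  check_same_shape(mask, field, "mask and field")
  out <- warp_image(mask, field, interpolation = "nearest")
  storage.mode(out) <- "integer"
  out
}

#' Overlap table between propagated and segmented masks
#'
#' Pixel-count table of co-occurring (propagated label, segmented label)
#' pairs, background excluded, with entries below `min_overlap_px` dropped.
#'
#' @param l_hat Propagated label mask.
#' @param l_seg Freshly segmented label mask.
#' @param min_overlap_px Minimum shared pixel count.
#' @return Tibble with columns `prop`, `seg`, `n`.
#' @export
overlap_table <- function(l_hat, l_seg, min_overlap_px = 1L) {
  check_same_shape(l_hat, l_seg, "masks")
  sel <- l_hat > 0 & l_seg > 0
  if (!any(sel)) {
    return(tibble::tibble(prop = integer(), seg = integer(), n = integer()))
  }
  tibble::tibble(prop = as.integer(l_hat[sel]), seg = as.integer(l_seg[sel])) |>
    dplyr::count(.data$prop, .data$seg, name = "n") |>
    dplyr::filter(.data$n >= min_overlap_px)
}

# Assign each TRUE pixel of `region` the label of the nearest labelled pixel
# among `labels` (restricted to `region`); ties go to the smaller label id.
assign_nearest_label <- function(region, labels) {
  out <- labels
  todo <- which(region & labels == 0)
  if (length(todo) == 0) return(out)
  src <- which(region & labels > 0)
  if (length(src) == 0) return(out)
  h <- nrow(labels)
  tr <- (todo - 1L) %% h + 1L; tc <- (todo - 1L) %/% h + 1L
  sr <- (src - 1L) %% h + 1L; sc <- (src - 1L) %/% h + 1L
  slab <- labels[src]
  ord <- order(slab)  # ascending label id: ties resolved to the smaller label
  sr <- sr[ord]; sc <- sc[ord]; slab <- slab[ord]
  for (i in seq_along(todo)) {
    d2 <- (sr - tr[i])^2 + (sc - tc[i])^2
    out[todo[i]] <- slab[which.min(d2)]
  }
  out
}

#' Reconcile propagated and segmented masks
#'
#' Fuses the displacement-propagated mask with the fresh segmentation into a
#' consistent labeling, classifying every correspondence:
#'
#' * **one-to-one**: the segmented shape is kept with the propagated label
#'   (`continue` event);
#' * **merge** (one segmented object covers several propagated labels): the
#'   propagated labels are kept and partition the segmented blob; pixels of
#'   the blob outside all propagated masks join the nearest propagated label
#'   (`merge` event from each parent);
#' * **split** (one propagated label covers several segmented objects): the
#'   segmented shapes are kept and each receives a fresh label (`split`
#'   events from the common parent);
#' * **new** (segmented object without significant propagated overlap): fresh
#'   label, `appear` event.
#'
#' Propagated labels without any segmented counterpart vanish (track ends).
#' Objects participating in both merge-like and split-like overlaps are
#' resolved merge-first; segmented objects whose only parents were consumed
#' by a merge are treated as new.
#'
#' @param l_hat Propagated label mask (labels from frame `t`).
#' @param l_seg Segmented label mask of frame `t + 1`.
#' @param next_free_label First integer available for new labels; must exceed
#'   every label in `l_hat`.
#' @param min_overlap_px Correspondence significance threshold (pixels).
#' @return List with `mask` (reconciled integer label matrix), `events`
#'   (tibble `parent_label`, `child_label`, `event`), and `next_free_label`.
#' @export
reconcile <- function(l_hat, l_seg, next_free_label, min_overlap_px = 10L) {
  check_same_shape(l_hat, l_seg, "masks")
  if (max(l_hat) >= next_free_label) {
    stopf("next_free_label (%d) must exceed all propagated labels", next_free_label)
  }
  ov <- overlap_table(l_hat, l_seg, min_overlap_px)
  h <- nrow(l_hat); w <- ncol(l_hat)
  out <- matrix(0L, h, w)
  events <- list()
  nxt <- as.integer(next_free_label)

  seg_ids <- setdiff(sort(unique(as.integer(l_seg))), 0L)
  parents_of <- split(ov$prop, ov$seg)        # seg id -> propagated labels
  children_of <- split(ov$seg, ov$prop)       # prop id -> seg ids

  consumed_prop <- integer(0)

  # -- merges first: segmented blobs covering >= 2 propagated labels
  merge_segs <- as.integer(names(parents_of)[lengths(parents_of) >= 2])
  for (b in merge_segs) {
    region <- l_seg == b
    parents <- sort(unique(parents_of[[as.character(b)]]))
    keep <- matrix(0L, h, w)
    sel <- region & (l_hat %in% parents)
    keep[sel] <- l_hat[sel]
    keep <- assign_nearest_label(region, keep)
    out[region] <- keep[region]
    for (p in parents) {
      events[[length(events) + 1]] <-
        list(parent_label = p, child_label = p, event = "merge", blob = b)
    }
    consumed_prop <- c(consumed_prop, parents)
  }

  # -- remaining propagated labels: split / one-to-one on residual overlaps
  rest_prop <- setdiff(as.integer(names(children_of)), consumed_prop)
  claimed_seg <- merge_segs
  for (a in sort(rest_prop)) {
    childs <- setdiff(sort(unique(children_of[[as.character(a)]])), claimed_seg)
    if (length(childs) == 0) next  # counterpart consumed by a merge
    if (length(childs) == 1) {
      b <- childs
      out[l_seg == b] <- a
      events[[length(events) + 1]] <-
        list(parent_label = a, child_label = a, event = "continue")
    } else {
      for (b in childs) {
        out[l_seg == b] <- nxt
        events[[length(events) + 1]] <-
          list(parent_label = a, child_label = nxt, event = "split")
        nxt <- nxt + 1L
      }
    }
    claimed_seg <- c(claimed_seg, childs)
  }

  # -- segmented objects with no (remaining) significant parent: new tracks
  for (b in setdiff(seg_ids, claimed_seg)) {
    out[l_seg == b] <- nxt
    events[[length(events) + 1]] <-
      list(parent_label = NA_integer_, child_label = nxt, event = "appear")
    nxt <- nxt + 1L
  }

  events <- if (length(events) == 0) {
    tibble::tibble(parent_label = integer(), child_label = integer(),
                   event = character(), blob = integer())
  } else {
    dplyr::bind_rows(lapply(events, function(e) {
      e$blob <- e$blob %||% NA_integer_
      tibble::as_tibble(e)
    }))
  }
  list(mask = out, events = events, next_free_label = nxt)
}

mask_centroids <- function(mask) {
  ids <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (length(ids) == 0) {
    return(tibble::tibble(label = integer(), centroid_row = numeric(),
                          centroid_col = numeric()))
  }
  h <- nrow(mask)
  nz <- which(mask > 0)
  r <- (nz - 1L) %% h + 1L; c <- (nz - 1L) %/% h + 1L
  lab <- as.integer(mask[nz])
  tibble::tibble(label = lab, r = r, c = c) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(centroid_row = mean(.data$r), centroid_col = mean(.data$c),
                     .groups = "drop")
}

#' Track colonies over a frame sequence
#'
#' Runs the full register/propagate/segment/reconcile loop over an ordered
#' frame sequence and assembles the lineage as a [track_graph()]. The first
#' processed frame is segmented from scratch; every later frame's
#' segmentation is initialized with the propagated mask. If a registration
#' fails on a pair, an identity (zero) field is substituted with a warning
#' and the sequence continues.
#'
#' With `direction = "backward"` the sequence is processed in reverse; output
#' masks and graph are re-indexed to the original frame order, and an event
#' detected as a split in processing order is reported as a forward-time
#' merge (and vice versa). The graph's `direction` field records the
#' processing direction; edges always point from the earlier to the later
#' original frame.
#'
#' @param frames List of frames (from [read_sequence()] or
#'   [generate_sequence()]) or plain `[0, 1]` matrices.
#' @param params A [tracking_params()] list.
#' @return List with `masks` (one integer label matrix per frame, original
#'   order), `fields` (list of `h x w x 2` arrays, `fields[[t]]` registering
#'   original frame `t` onto `t + 1`), and `graph` (a `track_graph`).
#' @export
track_sequence <- function(frames, params = tracking_params()) {
  stopifnot(inherits(params, "tracking_params"))
  n <- length(frames)
  if (n < 2) stopf("need at least 2 frames to track")
  px <- lapply(frames, frame_pixels)
  backward <- params$direction == "backward"
  if (backward) px <- rev(px)

  masks <- vector("list", n)
  fields <- vector("list", n - 1)
  masks[[1]] <- segment_colonies(px[[1]], params$segmentation)
  nxt <- max(masks[[1]]) + 1L
  all_events <- list()

  for (t in seq_len(n - 1)) {
    reg <- tryCatch(
      register_pair(px[[t]], px[[t + 1]], params$registration),
      error = function(e) {
        warning(sprintf("registration failed for pair %d->%d (%s); using identity field",
                        t, t + 1, conditionMessage(e)), call. = FALSE)
        NULL
      })
    field <- if (is.null(reg)) array(0, c(nrow(px[[t]]), ncol(px[[t]]), 2)) else reg$field
    if (!is.null(reg)) {
      mag <- max(sqrt(field[, , 1]^2 + field[, , 2]^2))
      if (mag > params$max_displacement_px) {
        warning(sprintf(
          "registration for pair %d->%d produced an implausible field (max %.1f px > %.1f); using identity field",
          t, t + 1, mag, params$max_displacement_px), call. = FALSE)
        field <- array(0, dim(field))
      }
    }
    fields[[t]] <- field
    l_hat <- propagate_labels(masks[[t]], field)
    # The propagated mask initializes the active contour, but the band-limited
    # contour evolution cannot seed objects the propagation missed (e.g. a
    # subcolony pinched off by a deformed field), so the initialization is the
    # union of the propagated support and an independent segmentation.
    l_cold <- segment_colonies(px[[t + 1]], params$segmentation)
    init <- matrix(as.integer(l_hat > 0 | l_cold > 0), nrow(l_hat), ncol(l_hat))
    if (!any(init > 0)) init <- NULL
    l_seg <- segment_colonies(px[[t + 1]], params$segmentation, init_mask = init)
    rec <- reconcile(l_hat, l_seg, nxt, params$min_overlap_px)
    masks[[t + 1]] <- rec$mask
    nxt <- rec$next_free_label
    ev <- rec$events
    # a "merge" whose parents were already one connected object in the
    # previous mask is an ongoing fused state, not a new fusion event
    if (any(ev$event == "merge")) {
      comp <- label_components(masks[[t]] > 0)
      for (b in unique(ev$blob[ev$event == "merge"])) {
        rows <- which(ev$event == "merge" & ev$blob == b)
        comp_ids <- vapply(ev$parent_label[rows], function(p) {
          px <- which(masks[[t]] == p)
          if (length(px) == 0) return(NA_integer_)
          as.integer(names(which.max(table(comp[px]))))
        }, integer(1))
        if (length(unique(stats::na.omit(comp_ids))) <= 1) {
          ev$event[rows] <- "continue"
        }
      }
    }
    ev$blob <- NULL
    if (nrow(ev) > 0) {
      ev$proc_step <- t
      all_events[[length(all_events) + 1]] <- ev
    }
  }
  events <- if (length(all_events) == 0) {
    tibble::tibble(parent_label = integer(), child_label = integer(),
                   event = character(), proc_step = integer())
  } else {
    dplyr::bind_rows(all_events)
  }

  # map processing index (1..n) to original frame index (0-based)
  orig_frame <- if (backward) rev(seq_len(n)) - 1L else seq_len(n) - 1L

  nodes <- dplyr::bind_rows(lapply(seq_len(n), function(t) {
    cen <- mask_centroids(masks[[t]])
    if (nrow(cen) == 0) return(NULL)
    tibble::tibble(frame = orig_frame[t], label = cen$label,
                   centroid_row = cen$centroid_row,
                   centroid_col = cen$centroid_col)
  }))
  if (is.null(nodes) || nrow(nodes) == 0) {
    nodes <- tibble::tibble(frame = integer(), label = integer(),
                            centroid_row = numeric(), centroid_col = numeric())
  } else {
    nodes <- dplyr::arrange(nodes, .data$frame, .data$label)
  }

  edges <- if (nrow(events) == 0) NULL else {
    ev <- events
    from_frame <- orig_frame[ev$proc_step]       # earlier in processing order
    to_frame <- orig_frame[ev$proc_step + 1L]    # later in processing order
    if (backward) {
      # Forward-time reading: the processing-order child sits at the earlier
      # original frame, so parent/child swap and merge/split exchange roles.
      # Processing-order appearances are forward-time track terminations and
      # yield no edge.
      keep <- ev$event != "appear"
      ev <- ev[keep, ]; from_frame <- from_frame[keep]; to_frame <- to_frame[keep]
      ev$event <- dplyr::recode(ev$event, split = "merge", merge = "split")
      tibble::tibble(
        parent_frame = to_frame,
        parent_label = ev$child_label,
        child_frame = from_frame,
        child_label = ev$parent_label,
        event = ev$event)
    } else {
      tibble::tibble(
        parent_frame = ifelse(is.na(ev$parent_label), NA_integer_, from_frame),
        parent_label = ev$parent_label,
        child_frame = to_frame,
        child_label = ev$child_label,
        event = ev$event)
    }
  }
  if (backward) {
    masks <- rev(masks)
    fields <- rev(fields)
  }
  graph <- track_graph(nodes, edges, direction = params$direction)
  list(masks = masks, fields = fields, graph = graph)
}
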