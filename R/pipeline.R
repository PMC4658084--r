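#' Run the full echogram-processing pipeline
#'
#' Applies the processing chain to a survey: stitch de-duplicated frames,
#' detect upper edges, trace the seabed, mask the sub-seabed signal,
#' despeckle, suppress interference columns, then detect, filter, aggregate
#' and measure schools. Optional declarative exclusion regions (replacing an
#' interactive review) are cleared before candidate detection.
#'
#' @param frames A list of [echogram_frame()] objects (de-duplicated), or a
#'   single stitched frame.
#' @param mapping [pixel_mapping()] used for the Sv exclusion threshold.
#' @param rules [aggregation_rules()].
#' @param lambda,P Seabed-tracer parameters (see [trace_seabed()]).
#' @param edge_threshold Minimum colour index counting as object edge.
#' @param despeckle_kernel Median-filter window (odd, >= 3).
#' @param z_threshold Noise-column robust z threshold.
#' @param seabed_margin_m Margin subtracted from the traced seabed before
#'   masking (m).
#' @param exclusions Optional data.frame (`row_min, row_max, col_min,
#'   col_max`) of regions (global stitched coordinates) cleared before
#'   candidate detection.
#' @return List: `schools` (school table; zero-row when none), `rejections`
#'   (rejection log), `seabed` (the [trace_seabed()] path), `removed_cols`
#'   (interference columns), `frame` (the processed stitched frame).
#' @export
process_survey <- function(frames, mapping,
                           rules = aggregation_rules(),
                           lambda = 0.5, P = 2L, edge_threshold = 1L,
                           despeckle_kernel = 3L, z_threshold = 5,
                           seabed_margin_m = 0, exclusions = NULL) {
  frame <- if (inherits(frames, "echogram_frame")) frames else stitch_frames(frames)
  edges <- detect_upper_edges(frame, edge_threshold)
  seabed <- trace_seabed(edges, lambda = lambda, P = P)
  masked <- mask_below_seabed(frame, seabed, margin_m = seabed_margin_m)
  clean <- despeckle(masked, despeckle_kernel)
  nc <- remove_noise_columns(clean, z_threshold)
  clean <- nc$frame
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      ex <- exclusions[i, ]
      clean$pixels[ex$row_min:ex$row_max, ex$col_min:ex$col_max] <- 0L
    }
  }
  mask <- make_mask(clean)
  cands <- find_candidates(mask, clean, seabed = seabed)
  filt <- filter_candidates(cands, rules, clean, mapping)
  schools <- link_schools(filt$retained, rules, clean)
  tab <- do.call(rbind, lapply(schools, extract_parameters,
                               frame = clean, seabed = seabed))
  if (is.null(tab)) {
    tab <- extract_parameters(
      list(rows = 1L, cols = 1L, n = 1L,
           bbox = c(minr = 1L, maxr = 1L, minc = 1L, maxc = 1L)),
      frame = clean, seabed = seabed)[0, ]
  }
  list(schools = tab, rejections = filt$rejected, seabed = seabed,
       removed_cols = nc$removed, frame = clean)
}
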