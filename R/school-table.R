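#' School descriptor table
#'
#' Schools are stored as a data.frame, one row per school, using the exact
#' CSV headers of the descriptor schema: `File, Time, Date, PicRef, Lat_dd,
#' Long_dd, LeftLat, LeftLon, RightLat, RightLon, BotAltitude, TopDepth,
#' MeanAltitude, MeanDepth, BotDepth, SchoolHeight, SchoolWidth, Area,
#' AreaLV, Perimeter, MaxCalDiam, MinCalDiam, MaxCalAngle`, plus one
#' pixel-count column per (retained) colour index, named `Px1`, `Px2`, ...
#' (index 0 is background and never occurs inside a school mask).
#'
#' @name school_table
NULL

school_cols <- c("File", "Time", "Date", "PicRef", "Lat_dd", "Long_dd",
                 "LeftLat", "LeftLon", "RightLat", "RightLon",
                 "BotAltitude", "TopDepth", "MeanAltitude", "MeanDepth",
                 "BotDepth", "SchoolHeight", "SchoolWidth", "Area", "AreaLV",
                 "Perimeter", "MaxCalDiam", "MinCalDiam", "MaxCalAngle")

px_cols <- function(n_colours) paste0("Px", seq_len(n_colours - 1L))

#' Validate a school table against the descriptor-schema invariants
#'
#' Checks depth ordering (`TopDepth <= MeanDepth <= BotDepth`), the
#' altitude/depth duality (`MeanAltitude = BotDepth - MeanDepth`), area
#' positivity and `AreaLV <= Area`, the caliper-diameter ordering, and that
#' pixel counts are non-negative.
#'
#' @param schools A school data.frame.
#' @param tol Numerical tolerance for the altitude duality.
#' @return `schools`, invisibly; errors describe the first violated rule.
#' @export
validate_school_table <- function(schools, tol = 1e-6) {
  miss <- setdiff(school_cols, names(schools))
  if (length(miss))
    stop("school table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(schools)) return(invisible(schools))
  with(schools, {
    if (any(TopDepth > MeanDepth + tol) || any(MeanDepth > BotDepth + tol))
      stop("depth ordering TopDepth <= MeanDepth <= BotDepth violated", call. = FALSE)
    if (any(TopDepth + SchoolHeight > BotDepth + tol))
      stop("school extends below the seabed", call. = FALSE)
    if (any(abs(MeanAltitude - (BotDepth - MeanDepth)) > tol))
      stop("MeanAltitude must equal BotDepth - MeanDepth", call. = FALSE)
    if (any(Area <= 0) || any(AreaLV <= 0) || any(AreaLV > Area + tol))
      stop("need 0 < AreaLV <= Area", call. = FALSE)
    if (any(MinCalDiam > MaxCalDiam + tol))
      stop("MinCalDiam must not exceed MaxCalDiam", call. = FALSE)
    if (any(MaxCalDiam + tol < pmax(SchoolWidth, SchoolHeight)))
      stop("MaxCalDiam must be >= max(SchoolWidth, SchoolHeight)", call. = FALSE)
  })
  pxc <- grep("^Px[0-9]+$", names(schools), value = TRUE)
  if (length(pxc)) {
    px <- as.matrix(schools[pxc])
    if (any(px < 0) || any(px != round(px)))
      stop("pixel counts must be non-negative integers", call. = FALSE)
  }
  invisible(schools)
}

#' Write / read a school descriptor CSV
#'
#' Round-trips are lossless for every schema field. On read, the header is
#' checked against the expected schema and any delta (missing or unknown
#' columns) is reported.
#'
#' @param schools School data.frame (see [school_table]).
#' @param path CSV path.
#' @return `read_school_table` returns the validated data.frame.
#' @export
write_school_table <- function(schools, path) {
  miss <- setdiff(school_cols, names(schools))
  if (length(miss))
    stop("school table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pxc <- grep("^Px[0-9]+$", names(schools), value = TRUE)
  utils::write.csv(schools[c(school_cols, pxc)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_school_table
#' @export
read_school_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(File = "character", Time = "character",
                                       Date = "character", PicRef = "character"))
  pxc <- grep("^Px[0-9]+$", names(df), value = TRUE)
  miss <- setdiff(school_cols, names(df))
  extra <- setdiff(names(df), c(school_cols, pxc))
  if (length(miss) || length(extra))
    stop("school table schema mismatch",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  validate_school_table(df)
  df
}
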