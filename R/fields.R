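#' Per-vertex scalar field
#'
#' One scalar per mesh vertex: conduction velocity (m/s) under one of three
#' rhythm protocols, or the frequency (1/s) of a pathological conduction
#' pattern (focal firing, localized rotational activation, localized
#' irregular activity). Missing measurements are `NA`.
#'
#' @param values numeric vector, one value per mesh vertex; `NA` allowed.
#' @param kind one of `"cv_af"`, `"cv_long_cl"`, `"cv_short_cl"` (m/s) or
#'   `"ff"`, `"lra"`, `"lia"` (1/s).
#' @return object of class `vertex_field`.
#' @export
vertex_field <- function(values, kind = c("cv_af", "cv_long_cl",
                                          "cv_short_cl", "ff", "lra", "lia")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE))
    stop("vertex_field: values must be >= 0")
  structure(list(values = values, kind = kind,
                 units = if (startsWith(kind, "cv")) "m/s" else "1/s"),
            class = "vertex_field")
}

#' @export
print.vertex_field <- function(x, ...) {
  cat("vertex_field '", x$kind, "' (", x$units, "): ", length(x$values),
      " vertices, median ", format(stats::median(x$values, na.rm = TRUE),
                                   digits = 3),
      if (anyNA(x$values)) paste0(", ", sum(is.na(x$values)), " missing"),
      "\n", sep = "")
  invisible(x)
}

#' Read / write a vertex field as CSV
#'
#' CSV schema `vertex_index,value` (1-based indices) with a comment header
#' line naming the kind and units.
#' @param path CSV path.
#' @param kind field kind (on read, used when no header comment names one).
#' @return a [vertex_field].
#' @export
read_vertex_field <- function(path, kind = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  if (is.null(kind) && length(meta) > 0) {
    m <- regmatches(meta[1], regexpr("kind=\\S+", meta[1]))
    if (length(m)) kind <- sub("kind=", "", m)
  }
  if (is.null(kind)) stop("read_vertex_field: field kind not given and not in header")
  dat <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  values <- numeric(max(dat$vertex_index))
  values[dat$vertex_index] <- dat$value
  vertex_field(values, kind)
}

#' @rdname read_vertex_field
#' @param field a [vertex_field].
#' @export
write_vertex_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", field$kind, " units=", field$units), con)
  utils::write.csv(data.frame(vertex_index = seq_along(field$values),
                              value = field$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' Nearest-neighbour transfer of a vertex field between meshes
#'
#' Each vertex of `to_mesh` receives the value of the nearest (Euclidean)
#' vertex of `from_mesh`; ties break to the lowest source index.
#'
#' @param field a [vertex_field] on `from_mesh`.
#' @param from_mesh,to_mesh co-registered [surface_mesh]es.
#' @return a [vertex_field] on `to_mesh`.
#' @export
nn_transfer <- function(field, from_mesh, to_mesh) {
  if (length(field$values) != nrow(from_mesh$vertices))
    stop("nn_transfer: field length (", length(field$values),
         ") does not match from_mesh vertex count (",
         nrow(from_mesh$vertices), ")")
  idx <- cpp_knn(from_mesh$vertices, to_mesh$vertices, 1L)$idx[, 1]
  vertex_field(field$values[idx], field$kind)
}

#' Area-weighted histogram of a vertex field
#'
#' Each vertex contributes its barycentric area share to the bin containing
#' its value. Values above `clip_max` and missing values are excluded; the
#' excluded area plus the binned area equals the total surface area.
#'
#' @param field a [vertex_field].
#' @param mesh the [surface_mesh] carrying the field.
#' @param bins strictly increasing bin edges (values on an edge fall into
#'   the right bin, as `[e_k, e_{k+1})`; the last bin is closed).
#' @param clip_max exclusion threshold; default 1.5 m/s for conduction
#'   velocity kinds, none otherwise.
#' @return list with `bin_edges`, `area` (mm^2 per bin), `excluded_area`.
#' @export
area_histogram <- function(field, mesh, bins, clip_max = NULL) {
  if (is.unsorted(bins, strictly = TRUE))
    stop("area_histogram: bins must be strictly increasing")
  if (is.null(clip_max) && startsWith(field$kind, "cv")) clip_max <- 1.5
  w <- vertex_areas(mesh)
  v <- field$values
  ok <- !is.na(v)
  if (!is.null(clip_max)) ok <- ok & v <= clip_max
  nb <- length(bins) - 1L
  idx <- findInterval(v[ok], bins, rightmost.closed = TRUE)
  inb <- idx >= 1L & idx <= nb
  area <- vapply(seq_len(nb), function(k) sum(w[ok][inb & idx == k]), 0)
  list(bin_edges = bins, area = area,
       excluded_area = sum(w) - sum(area))
}

#' Correlation between two paired vertex fields
#'
#' Pearson (with Fisher-z 95 percent confidence interval) or Spearman,
#' computed as average-rank transform followed by the Pearson machinery.
#' Missing values are deleted pairwise.
#'
#' @param x,y [vertex_field]s (or numeric vectors) of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `conf_int` (95 percent), `p_value`,
#'   `n`, `method`.
#' @export
paired_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- if (inherits(x, "vertex_field")) x$values else as.numeric(x)
  yv <- if (inherits(y, "vertex_field")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("paired_correlation: length mismatch")
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("paired_correlation: fewer than 3 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("paired_correlation: zero variance in an input")
  if (method == "spearman") { xv <- rank(xv); yv <- rank(yv) }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA, NA)
  list(estimate = unname(ct$estimate), conf_int = ci,
       p_value = ct$p.value, n = length(xv), method = method)
}

#' Per-vertex distance to an adjacent structure
#'
#' Euclidean distance from each vertex of the chamber mesh to the closest
#' point on the structure's triangles (surface points, not only vertices).
#' Both meshes must be in the co-registered frame: move the structure with
#' the same transform that registered the chamber reconstruction.
#'
#' @param la_mesh the chamber [surface_mesh].
#' @param structure the adjacent structure [surface_mesh].
#' @param structure_label optional label (e.g. `"ascending_aorta"`,
#'   `"descending_aorta"`, `"spine"`).
#' @return object of class `proximity_result`: list with `distances` (mm),
#'   `structure_label`, `contact` (`NULL` until [contact_mask] is applied).
#' @export
structure_distance <- function(la_mesh, structure, structure_label = "other") {
  if (nrow(structure$faces) == 0L)
    stop("structure_distance: empty structure mesh")
  d <- mesh_closest_points(structure, la_mesh$vertices)$dist
  structure(list(distances = d, structure_label = structure_label,
                 contact = NULL, threshold_mm = NULL),
            class = "proximity_result")
}

#' Flag contact vertices by a distance threshold
#'
#' A vertex is in contact when its distance is within the threshold
#' (inclusive: `distance <= threshold`). Given several proximity results
#' (multiple structures), a vertex is in contact if it is within the
#' threshold of any structure.
#'
#' @param pr a `proximity_result`, or a list of them.
#' @param threshold mm (default 3).
#' @return a `proximity_result` with `contact` flags (for a list input, the
#'   distances are the per-vertex minima over structures).
#' @export
contact_mask <- function(pr, threshold = 3) {
  if (inherits(pr, "proximity_result")) {
    pr$contact <- pr$distances <= threshold
    pr$threshold_mm <- threshold
    return(pr)
  }
  stopifnot(length(pr) >= 1L)
  d <- do.call(pmin, lapply(pr, `[[`, "distances"))
  structure(list(distances = d,
                 structure_label = paste(vapply(pr, `[[`, "", "structure_label"),
                                         collapse = "+"),
                 contact = d <= threshold, threshold_mm = threshold),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat("proximity to ", x$structure_label, ": min ",
      format(min(x$distances), digits = 3), " mm, median ",
      format(stats::median(x$distances), digits = 3), " mm", sep = "")
  if (!is.null(x$contact))
    cat("; ", sum(x$contact), "/", length(x$contact), " vertices in contact (<= ",
        x$threshold_mm, " mm)", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a proximity result as CSV
#'
#' Schema `vertex_index,distance_mm,contact`.
#' @param pr a `proximity_result` (after [contact_mask]).
#' @param path output CSV path.
#' @export
write_proximity <- function(pr, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(pr$distances),
                              distance_mm = pr$distances,
                              contact = if (is.null(pr$contact)) NA
                                        else pr$contact),
                   path, row.names = FALSE)
  invisible(path)
}

#' Compare a vertex field between contact and non-contact vertices
#'
#' Mann-Whitney U test of the field values at contact versus non-contact
#' vertices: exact for pooled n <= 20 (without ties), normal approximation
#' with continuity and tie correction otherwise; two-sided. Group summaries
#' are median and interquartile range.
#'
#' @param field a [vertex_field] (or numeric vector).
#' @param contact logical vector (or a `proximity_result` carrying one).
#' @return object of class `group_comparison`: medians and IQRs per group,
#'   `U` statistic (contact group), two-sided `p_value`, group sizes.
#' @export
compare_by_contact <- function(field, contact) {
  v <- if (inherits(field, "vertex_field")) field$values else as.numeric(field)
  if (inherits(contact, "proximity_result")) contact <- contact$contact
  if (is.null(contact)) stop("compare_by_contact: contact flags missing; run contact_mask first")
  if (length(v) != length(contact))
    stop("compare_by_contact: field length (", length(v),
         ") does not match contact flag length (", length(contact), ")")
  ok <- !is.na(v)
  v <- v[ok]; contact <- contact[ok]
  g1 <- v[contact]; g0 <- v[!contact]
  if (length(g1) == 0L) stop("compare_by_contact: contact group is empty")
  if (length(g0) == 0L) stop("compare_by_contact: non-contact group is empty")
  pooled <- length(g1) + length(g0)
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g0, exact = pooled <= 20, correct = TRUE))
  q1 <- stats::quantile(g1, c(0.25, 0.5, 0.75), names = FALSE)
  q0 <- stats::quantile(g0, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    median_contact = q1[2], iqr_contact = q1[c(1, 3)],
    median_noncontact = q0[2], iqr_noncontact = q0[c(1, 3)],
    U = unname(wt$statistic), p_value = wt$p.value,
    n_contact = length(g1), n_noncontact = length(g0)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(m, q) paste0(format(m, digits = 3), " (IQR ",
                               format(q[1], digits = 3), "-",
                               format(q[2], digits = 3), ")")
  cat("contact (n=", x$n_contact, "): ",
      fmt(x$median_contact, x$iqr_contact), "\n", sep = "")
  cat("non-contact (n=", x$n_noncontact, "): ",
      fmt(x$median_noncontact, x$iqr_noncontact), "\n", sep = "")
  cat("Mann-Whitney U = ", format(x$U), ", two-sided p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Paired t test on per-case values
#'
#' Standard paired Student's t on the differences, df = n - 1, two-sided
#' (used e.g. for per-case chamber volumes from two modalities).
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return list with `t`, `p_value`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("paired_t_test: length mismatch")
  if (length(x) < 2L) stop("paired_t_test: needs n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("paired_t_test: differences have zero variance; t is undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate))
}
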