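#' Define a site of metabolism for pose classification
#'
#' Names the atoms needed to decide whether an enzyme-substrate frame is a
#' catalytically active (near-attack) pose for hydroxylation at one site of
#' metabolism (SOM). Aromatic hydroxylation is judged on the SOM carbon,
#' SOM hydrogen and ferryl oxygen; aliphatic hydrogen abstraction on the
#' SOM hydrogen, ferryl oxygen and heme iron.
#'
#' @param label SOM label (e.g. `"4'"`, `"15b"`).
#' @param type `"aromatic"` or `"aliphatic"`.
#' @param C_som,H_som,O_ferryl,Fe Role names, i.e. values of the `role`
#'   column of the frame table, for each required atom.
#' @return An object of class `som_definition`.
#' @examples
#' som_definition("4'", "aromatic")
#' @export
som_definition <- function(label, type = c("aromatic", "aliphatic"),
                           C_som = "C_som", H_som = "H_som",
                           O_ferryl = "O_ferryl", Fe = "Fe") {
  type <- rlang::arg_match(type)
  structure(list(label = as.character(label), type = type,
                 roles = c(C_som = C_som, H_som = H_som,
                           O_ferryl = O_ferryl, Fe = Fe)),
            class = "som_definition")
}

#' @export
print.som_definition <- function(x, ...) {
  cat(sprintf("SOM \"%s\" (%s hydroxylation)\n", x$label, x$type))
  cat("  roles:", paste(names(x$roles), x$roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Geometric pose-classification criteria
#'
#' Distance and angle thresholds that define a catalytically active pose.
#' Aromatic sites: SOM-carbon-to-ferryl-oxygen distance below the cutoff and
#' the C-H-O angle outside the excluded interval (hydrogen interposition
#' between the ferryl oxygen and the attacked carbon blocks the reaction).
#' Aliphatic sites: SOM-hydrogen-to-ferryl-oxygen distance below the cutoff
#' and the H-O-Fe angle inside the window.
#'
#' Three-point angles lie in \[0, 180\] degrees; an excluded interval
#' extending beyond 180 (such as the default 140-220) is applied through the
#' reflection 360 - angle, so the default exclusion is effectively
#' angle >= 140. Distances compare strictly (`< cutoff`); angle windows are
#' closed (inclusive).
#'
#' @param distance_cutoff Distance cutoff in nm (default 0.35).
#' @param aromatic_excluded_angle Excluded C-H-O interval in degrees
#'   (default `c(140, 220)`).
#' @param aliphatic_angle_window Allowed H-O-Fe interval in degrees
#'   (default `c(110, 130)`).
#' @return An object of class `pose_criteria`.
#' @export
pose_criteria <- function(distance_cutoff = 0.35,
                          aromatic_excluded_angle = c(140, 220),
                          aliphatic_angle_window = c(110, 130)) {
  check_number(distance_cutoff, "distance_cutoff", positive = TRUE)
  for (iv in list(aromatic_excluded_angle, aliphatic_angle_window)) {
    if (length(iv) != 2 || iv[1] > iv[2]) {
      abort_usage("Angle intervals must be ordered length-2 vectors.")
    }
  }
  structure(list(distance_cutoff = distance_cutoff,
                 aromatic_excluded_angle = aromatic_excluded_angle,
                 aliphatic_angle_window = aliphatic_angle_window),
            class = "pose_criteria")
}

#' Read per-frame pose coordinates from delimited text
#'
#' One row per frame per atom role, columns `frame`, `role`, `x`, `y`, `z`
#' and optionally `trajectory`. The length unit is never inferred: it must
#' be declared (`"nm"` or `"angstrom"`; angstrom input is converted by 0.1).
#'
#' @param path Delimited text file (comma or tab).
#' @param unit Length unit of the coordinates. No default.
#' @return Tibble with columns `trajectory` (if present), `frame`, `role`,
#'   `x`, `y`, `z` in nanometres.
#' @export
read_pose_frames <- function(path, unit) {
  if (missing(unit)) {
    abort_usage("The coordinate `unit` must be declared (\"nm\" or \"angstrom\").")
  }
  unit <- rlang::arg_match(unit, c("nm", "angstrom"))
  raw <- read_delimited_chr(path, what = "Pose frame table")
  require_columns(raw, c("frame", "role", "x", "y", "z"), "Pose frame table")
  out <- tibble::tibble(
    frame = as.integer(parse_numeric_col(raw$frame, "frame", raw$.line)),
    role = as.character(raw$role),
    x = parse_numeric_col(raw$x, "x", raw$.line),
    y = parse_numeric_col(raw$y, "y", raw$.line),
    z = parse_numeric_col(raw$z, "z", raw$.line))
  if ("trajectory" %in% names(raw)) {
    out <- tibble::add_column(out, trajectory = as.character(raw$trajectory),
                              .before = 1)
  }
  if (unit == "angstrom") {
    out <- dplyr::mutate(out, dplyr::across(c("x", "y", "z"), ~ .x * 0.1))
  }
  out
}

#' Read multi-frame XYZ coordinates with a role mapping
#'
#' Parses a concatenated XYZ file (per frame: an atom-count line, a comment
#' line, then one `element x y z` line per atom) and keeps only the atoms
#' named in `role_map`. Binary trajectory formats are out of scope; convert
#' externally (e.g. with an MD analysis toolkit) to XYZ or to the delimited
#' layout of [read_pose_frames()].
#'
#' @param path XYZ file.
#' @param role_map Named integer vector: role name -> 1-based atom index
#'   within each frame (e.g. `c(Fe = 1, O_ferryl = 2, C_som = 3, H_som = 4)`).
#' @param unit Length unit, `"nm"` or `"angstrom"` (most XYZ files are
#'   angstrom); never inferred.
#' @return Long tibble as from [read_pose_frames()].
#' @export
read_xyz_frames <- function(path, role_map, unit) {
  if (missing(unit)) {
    abort_usage("The coordinate `unit` must be declared (\"nm\" or \"angstrom\").")
  }
  unit <- rlang::arg_match(unit, c("nm", "angstrom"))
  if (is.null(names(role_map)) || any(!nzchar(names(role_map)))) {
    abort_usage("`role_map` must be a named vector of atom indices.")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort_format("XYZ file is empty.")
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) {
      abort_parse(sprintf("Expected an atom count at line %d.", i))
    }
    if (i + 1L + nat > length(lines)) {
      abort_parse(sprintf("Truncated XYZ frame starting at line %d.", i))
    }
    frame <- frame + 1L
    body <- lines[(i + 2L):(i + 1L + nat)]
    if (any(role_map > nat)) {
      abort_validation(sprintf("role_map index exceeds %d atoms in frame %d.",
                               nat, frame))
    }
    fields <- strsplit(trimws(body[role_map]), "\\s+")
    coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(coords)) {
      abort_parse(sprintf("Non-numeric coordinates in frame %d.", frame))
    }
    out[[frame]] <- tibble::tibble(frame = frame, role = names(role_map),
                                   x = coords[, 1], y = coords[, 2],
                                   z = coords[, 3])
    i <- i + 2L + nat
  }
  res <- dplyr::bind_rows(out)
  if (unit == "angstrom") {
    res <- dplyr::mutate(res, dplyr::across(c("x", "y", "z"), ~ .x * 0.1))
  }
  res
}

# Wide per-frame coordinates for the roles a SOM needs; errors name the
# missing role and the frame rather than silently skipping (a silent skip
# would bias active fractions).
frame_coords <- function(frames, som) {
  require_columns(frames, c("frame", "role", "x", "y", "z"), "Frame table")
  needed <- if (som$type == "aromatic") {
    som$roles[c("C_som", "H_som", "O_ferryl")]
  } else {
    som$roles[c("H_som", "O_ferryl", "Fe")]
  }
  sub <- dplyr::filter(frames, .data$role %in% needed)
  wide <- tidyr::pivot_wider(sub, id_cols = "frame", names_from = "role",
                             values_from = c("x", "y", "z"))
  for (role in needed) {
    cols <- paste(c("x", "y", "z"), role, sep = "_")
    if (!all(cols %in% names(wide))) {
      abort_validation(sprintf("Role \"%s\" is missing from every frame.", role))
    }
    bad <- which(!stats::complete.cases(wide[cols]))
    if (length(bad) > 0) {
      abort_validation(sprintf("Role \"%s\" is missing in frame %d.",
                               role, wide$frame[bad[1]]))
    }
  }
  if (!all(is.finite(as.matrix(wide[setdiff(names(wide), "frame")])))) {
    abort_validation("Non-finite coordinates in frame table.")
  }
  list(wide = wide, roles = needed)
}

role_xyz <- function(wide, role) {
  as.matrix(wide[paste(c("x", "y", "z"), role, sep = "_")])
}

vec_angle_deg <- function(a, vertex, c) {
  u <- a - vertex
  v <- c - vertex
  num <- rowSums(u * v)
  den <- sqrt(rowSums(u^2) * rowSums(v^2))
  acos(pmin(pmax(num / den, -1), 1)) * 180 / pi
}

#' Per-frame SOM geometry
#'
#' Computes, for every frame, the distance and angle on which the active
#' pose decision rests: for an aromatic SOM the C_som-O_ferryl distance and
#' the C_som-H_som-O_ferryl angle (vertex at the hydrogen); for an aliphatic
#' SOM the H_som-O_ferryl distance and the H_som-O_ferryl-Fe angle (vertex
#' at the ferryl oxygen). Angles are three-point angles in \[0, 180\]
#' degrees; distances in nm.
#'
#' @param frames Long frame tibble ([read_pose_frames()],
#'   [read_xyz_frames()] or [simulate_poses()]).
#' @param som A [som_definition()].
#' @return Tibble with columns `frame`, `distance_nm`, `angle_deg`.
#' @export
frame_geometry <- function(frames, som) {
  if (!inherits(som, "som_definition")) abort_usage("`som` must be a som_definition.")
  fc <- frame_coords(frames, som)
  wide <- fc$wide
  if (som$type == "aromatic") {
    C <- role_xyz(wide, som$roles[["C_som"]])
    H <- role_xyz(wide, som$roles[["H_som"]])
    O <- role_xyz(wide, som$roles[["O_ferryl"]])
    dist <- sqrt(rowSums((C - O)^2))
    ang <- vec_angle_deg(C, H, O)
  } else {
    H <- role_xyz(wide, som$roles[["H_som"]])
    O <- role_xyz(wide, som$roles[["O_ferryl"]])
    Fe <- role_xyz(wide, som$roles[["Fe"]])
    dist <- sqrt(rowSums((H - O)^2))
    ang <- vec_angle_deg(H, O, Fe)
  }
  tibble::tibble(frame = wide$frame, distance_nm = dist, angle_deg = ang) |>
    dplyr::arrange(.data$frame)
}

# TRUE when a three-point angle falls in the excluded interval, applying
# the reflection 360 - angle for interval parts beyond 180 degrees.
angle_excluded <- function(angle, interval) {
  (angle >= interval[1] & angle <= interval[2]) |
    ((360 - angle) >= interval[1] & (360 - angle) <= interval[2])
}

#' Classify frames as catalytically active poses
#'
#' Applies the geometric near-attack criteria to every frame: an aromatic
#' SOM is active when its distance is below the cutoff and its C-H-O angle
#' is outside the excluded interval; an aliphatic SOM when its distance is
#' below the cutoff and its H-O-Fe angle lies within the window.
#'
#' @inheritParams frame_geometry
#' @param criteria A [pose_criteria()]; defaults to the standard thresholds.
#' @return The [frame_geometry()] tibble plus a logical `active` column.
#' @export
classify_poses <- function(frames, som, criteria = pose_criteria()) {
  if (!inherits(criteria, "pose_criteria")) {
    abort_usage("`criteria` must be a pose_criteria object.")
  }
  geo <- frame_geometry(frames, som)
  ok_dist <- geo$distance_nm < criteria$distance_cutoff
  ok_angle <- if (som$type == "aromatic") {
    !angle_excluded(geo$angle_deg, criteria$aromatic_excluded_angle)
  } else {
    geo$angle_deg >= criteria$aliphatic_angle_window[1] &
      geo$angle_deg <= criteria$aliphatic_angle_window[2]
  }
  dplyr::mutate(geo, active = ok_dist & ok_angle)
}

#' Active-pose fractions per trajectory and SOM
#'
#' Tabulates the percentage of frames classified as catalytically active
#' for each SOM, per trajectory (trajectories are never pooled silently:
#' rows stay separate, as in per-simulation reporting of MD results).
#'
#' @inheritParams classify_poses
#' @param soms A single [som_definition()] or a list of them.
#' @return Tibble with columns `trajectory`, `som`, `type`, `n_frames`,
#'   `n_active`, `percent_active`.
#' @examples
#' sim <- simulate_poses(n_frames = 50, target_fraction = 60, seed = 1)
#' active_fraction(sim$frames, sim$soms)
#' @export
active_fraction <- function(frames, soms, criteria = pose_criteria()) {
  if (inherits(soms, "som_definition")) soms <- list(soms)
  if (nrow(frames) == 0) abort_validation("Empty trajectory.")
  if (!"trajectory" %in% names(frames)) frames$trajectory <- "A"
  purrr::map(soms, function(som) {
    som_label <- som$label
    som_type <- som$type
    frames |>
      dplyr::group_by(.data$trajectory) |>
      dplyr::group_modify(function(g, k) {
        cls <- classify_poses(g, som, criteria)
        tibble::tibble(som = som_label, type = som_type,
                       n_frames = nrow(cls), n_active = sum(cls$active),
                       percent_active = 100 * mean(cls$active))
      }) |>
      dplyr::ungroup()
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$trajectory, .data$som)
}
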