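# Evaluate code with a locally-set RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default shared Vmax envelope: rise-and-fall with temperature
#'
#' A Gaussian bell in temperature, peaking near the enzyme's optimum,
#' emulating the factors (redox-partner coupling, membrane fluidity,
#' denaturation at high temperature) that depress absolute Vmax at both
#' temperature extremes but act on parallel pathways alike, and therefore
#' cancel in pathway ratios.
#'
#' @param peak Peak height (velocity units, default 600).
#' @param T_opt Temperature of maximal activity in K (default 297).
#' @param width Bell width in K (default 15).
#' @return A function of temperature (K).
#' @export
bell_envelope <- function(peak = 600, T_opt = 297, width = 15) {
  function(temperature_K) peak * exp(-((temperature_K - T_opt)^2) / (2 * width^2))
}

#' Simulate temperature-dependent multi-pathway kinetics with known truth
#'
#' Generates Michaelis-Menten velocity data for parallel product pathways
#' whose Vmax values follow
#' \eqn{V_{max,i}(T) = env(T) \, A_{rel,i} \, e^{-G_{eff,i}/(RT)}},
#' i.e. the modified Arrhenius model run forwards: for any pair (i, j) the
#' ratio series has exact slope \eqn{-(G_{eff,i}-G_{eff,j})/(R \cdot 10^3)}
#' and intercept \eqn{\ln(A_{rel,i}/A_{rel,j})}, while the shared envelope
#' — which models the strongly nonlinear single-pathway Arrhenius plots —
#' cancels in every ratio.
#'
#' Noise is multiplicative Gaussian on velocity,
#' \eqn{v = v_{true}(1+\epsilon)}, \eqn{\epsilon \sim N(0, cv)} truncated at
#' -0.99, reflecting roughly proportional published standard errors.
#'
#' Defaults mirror a typical temperature-dependence study of P450
#' hydroxylation: eight incubation temperatures spanning 277-318 K, seven
#' substrate concentrations from 10 to 750 uM, two pathways separated by
#' 8.1 kJ/mol in effective energy and 3.0 in log collision efficiency.
#'
#' @param temperatures Incubation temperatures in K.
#' @param pathways Data frame with columns `label`, `A_rel` (relative
#'   pre-exponential factor, > 0), `G_eff` (effective energy, kJ/mol) and
#'   `KM` (uM).
#' @param substrate_uM Substrate concentrations (uM).
#' @param envelope Shared multiplicative envelope: a function of
#'   temperature (K), or `NULL` for a constant 600.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noise-free).
#' @param n_replicates Replicate observations per concentration.
#' @param seed Optional integer seed (local to this call).
#' @return A list: `velocities` (tibble: `temperature_K`, `substrate_uM`,
#'   `metabolite`, `velocity`, `replicate`) and `truth` (tibble:
#'   `temperature_K`, `metabolite`, `Vmax`, `KM`), plus the generating
#'   configuration as attribute `config`.
#' @examples
#' sim <- simulate_kinetics(noise_cv = 0, n_replicates = 1)
#' fit_kinetics(sim$velocities)
#' @export
simulate_kinetics <- function(temperatures = c(277.0, 283.4, 290.2, 292.7,
                                               298.6, 304.4, 313.3, 317.6),
                              pathways = default_pathways(),
                              substrate_uM = c(10, 25, 50, 100, 250, 500, 750),
                              envelope = NULL,
                              noise_cv = 0.05,
                              n_replicates = 3,
                              seed = NULL) {
  check_number(temperatures, "temperatures", positive = TRUE)
  if (anyDuplicated(temperatures) > 0) {
    abort_validation("Temperatures must be distinct.")
  }
  require_columns(pathways, c("label", "A_rel", "G_eff", "KM"), "Pathway table")
  check_number(pathways$A_rel, "A_rel", positive = TRUE)
  check_number(pathways$G_eff, "G_eff")
  check_number(pathways$KM, "KM", positive = TRUE)
  check_number(substrate_uM, "substrate_uM", positive = TRUE)
  if (noise_cv < 0) abort_validation("`noise_cv` must be >= 0.")
  if (n_replicates < 1) abort_validation("`n_replicates` must be >= 1.")
  env_fn <- envelope %||% function(temperature_K) rep(600, length(temperature_K))

  truth <- tidyr::expand_grid(
    temperature_K = temperatures,
    metabolite = pathways$label) |>
    dplyr::left_join(
      dplyr::select(pathways, metabolite = "label", "A_rel", "G_eff", "KM"),
      by = "metabolite") |>
    dplyr::mutate(
      Vmax = env_fn(.data$temperature_K) * .data$A_rel *
        exp(-.data$G_eff / (R_GAS_KJ * .data$temperature_K))) |>
    dplyr::select("temperature_K", "metabolite", "Vmax", "KM")

  grid <- tidyr::expand_grid(
    truth,
    substrate_uM = substrate_uM,
    replicate = seq_len(n_replicates)) |>
    dplyr::mutate(v_true = .data$Vmax * .data$substrate_uM /
                    (.data$KM + .data$substrate_uM))

  eps <- local_seed(seed, rnorm(nrow(grid), 0, noise_cv))
  eps <- pmax(eps, -0.99)
  velocities <- grid |>
    dplyr::transmute(
      temperature_K = .data$temperature_K,
      substrate_uM = .data$substrate_uM,
      metabolite = .data$metabolite,
      velocity = .data$v_true * (1 + eps),
      replicate = .data$replicate)

  out <- list(velocities = velocities, truth = truth)
  attr(out, "config") <- list(temperatures = temperatures, pathways = pathways,
                              substrate_uM = substrate_uM,
                              noise_cv = noise_cv,
                              n_replicates = n_replicates, seed = seed)
  out
}

#' Default two-pathway generator configuration
#'
#' Two parallel pathways separated by 8.1 kJ/mol in effective energy and
#' by 3.0 in log relative collision efficiency, with Michaelis constants in
#' the 100-150 uM range — the scale of a P450 regioselectivity study.
#'
#' @return A tibble with columns `label`, `A_rel`, `G_eff`, `KM`.
#' @export
default_pathways <- function() {
  tibble::tibble(label = c("P1", "P2"),
                 A_rel = c(exp(3), 1),
                 G_eff = c(8.1, 0),
                 KM = c(120, 150))
}

#' Simulate pose trajectories with controlled active fractions
#'
#' Builds per-frame atomic coordinates whose classification under the
#' geometric near-attack criteria is known by construction: for each SOM,
#' exactly `round(n_frames * target/100)` frames are placed (in seeded
#' random order) to satisfy the criteria and the rest to violate them, with
#' a safety margin of at least three times the coordinate jitter before the
#' jitter is added. Each frame then receives a random rigid rotation and
#' translation, so no laboratory-frame structure survives.
#'
#' Inactive frames violate either the distance criterion or the angle
#' criterion (chosen at random), exercising both branches of the classifier.
#'
#' @param n_frames Number of frames.
#' @param target_fraction Percent of active frames per SOM, in \[0, 100\];
#'   a scalar is recycled, or a vector named by SOM label.
#' @param soms List of [som_definition()]s; the default is one aromatic and
#'   one aliphatic SOM sharing the Fe and ferryl-oxygen atoms.
#' @param jitter Gaussian positional noise sd per coordinate, nm.
#' @param criteria [pose_criteria()] the construction must respect.
#' @param seed Optional integer seed (local to this call).
#' @return A list: `frames` (long tibble `frame`, `role`, `x`, `y`, `z`,
#'   nm), `labels` (tibble `frame`, `som`, `active` - the construction
#'   ground truth), `soms`, `criteria`.
#' @examples
#' sim <- simulate_poses(n_frames = 100, target_fraction = 60, seed = 7)
#' active_fraction(sim$frames, sim$soms)
#' @export
simulate_poses <- function(n_frames = 100, target_fraction = 60,
                           soms = NULL, jitter = 0.002,
                           criteria = pose_criteria(), seed = NULL) {
  if (n_frames < 1) abort_validation("`n_frames` must be >= 1.")
  if (any(target_fraction < 0 | target_fraction > 100)) {
    abort_validation("`target_fraction` must lie in [0, 100].")
  }
  if (jitter < 0) abort_validation("`jitter` must be >= 0.")
  soms <- soms %||% list(
    som_definition("arom", "aromatic", C_som = "C_arom", H_som = "H_arom"),
    som_definition("aliph", "aliphatic", C_som = "C_aliph", H_som = "H_aliph"))
  labels_som <- vapply(soms, function(s) s$label, character(1))
  frac <- if (is.null(names(target_fraction))) {
    setNames(rep_len(target_fraction, length(soms)), labels_som)
  } else {
    if (!all(labels_som %in% names(target_fraction))) {
      abort_usage("`target_fraction` names must cover every SOM label.")
    }
    target_fraction[labels_som]
  }

  local_seed(seed, {
    lab_list <- lapply(labels_som, function(lb) {
      n_act <- round(n_frames * frac[[lb]] / 100)
      sample(c(rep(TRUE, n_act), rep(FALSE, n_frames - n_act)))
    })
    names(lab_list) <- labels_som

    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      atoms <- build_frame_atoms(soms, vapply(lab_list, `[[`, logical(1), f),
                                 criteria, jitter)
      atoms <- rigid_motion(atoms)
      if (jitter > 0) {
        atoms$x <- atoms$x + rnorm(nrow(atoms), 0, jitter)
        atoms$y <- atoms$y + rnorm(nrow(atoms), 0, jitter)
        atoms$z <- atoms$z + rnorm(nrow(atoms), 0, jitter)
      }
      atoms$frame <- f
      frames[[f]] <- atoms
    }

    labels <- tidyr::expand_grid(frame = seq_len(n_frames), som = labels_som) |>
      dplyr::mutate(active = purrr::map2_lgl(.data$som, .data$frame,
                                             ~ lab_list[[.x]][.y]))
    list(frames = dplyr::bind_rows(frames)[c("frame", "role", "x", "y", "z")],
         labels = dplyr::arrange(labels, .data$frame, .data$som),
         soms = soms, criteria = criteria)
  })
}

# One frame's atoms in a local axis system: ferryl O at the origin, Fe on
# the -x axis at the Fe=O bond length; each SOM's substrate atoms are placed
# to satisfy or violate its criteria with margin >= 3 x jitter.
build_frame_atoms <- function(soms, active, criteria, jitter) {
  d_fe_o <- 0.162   # ferryl Fe=O bond, nm
  b_ch <- 0.109     # C-H bond, nm
  m_d <- max(0.03, 6 * jitter)           # distance margin
  m_a <- max(8, 2000 * jitter)           # angle margin, degrees
  cut <- criteria$distance_cutoff
  rows <- list(tibble::tibble(role = c("Fe", "O_ferryl"),
                              x = c(-d_fe_o, 0), y = 0, z = 0))
  for (i in seq_along(soms)) {
    som <- soms[[i]]
    act <- active[[som$label]]
    # each SOM occupies its own plane about the Fe=O axis (rotations about
    # that axis preserve every criterion geometry), so SOMs never collide
    az <- 2 * pi * (i - 1) / length(soms)
    if (som$type == "aromatic") {
      excl_lo <- min(criteria$aromatic_excluded_angle[1],
                     360 - criteria$aromatic_excluded_angle[2])
      if (act) {
        theta <- runif(1, 15, excl_lo - m_a)
        d <- runif(1, 0.18, cut - m_d)
      } else if (runif(1) < 0.5) {          # distance violation
        theta <- runif(1, 15, excl_lo - m_a)
        d <- runif(1, cut + m_d, cut + 0.2)
      } else {                              # hydrogen interposition
        theta <- runif(1, excl_lo + m_a, 180)
        d <- runif(1, 0.18, cut - m_d)
      }
      th <- theta * pi / 180
      s <- b_ch * cos(th) + sqrt(d^2 - (b_ch * sin(th))^2)
      h <- c(s, 0, 0)
      cc <- h + b_ch * c(-cos(th), sin(th), 0)
      xyz <- rot_x(az, rbind(h, cc))
      rows[[length(rows) + 1]] <- tibble::tibble(
        role = unname(som$roles[c("H_som", "C_som")]),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    } else {
      win <- criteria$aliphatic_angle_window
      m_w <- min(m_a, (win[2] - win[1]) / 2 - 1)
      if (act) {
        phi <- runif(1, win[1] + m_w, win[2] - m_w)
        d <- runif(1, 0.18, cut - m_d)
      } else if (runif(1) < 0.5) {          # distance violation
        phi <- runif(1, win[1] + m_w, win[2] - m_w)
        d <- runif(1, cut + m_d, cut + 0.2)
      } else {                              # angle violation
        lo_len <- max(win[1] - m_a - 20, 0)
        phi <- if (runif(1) < 0.5 && lo_len > 0) {
          runif(1, max(win[1] - m_a - 30, 20), win[1] - m_a)
        } else {
          runif(1, win[2] + m_a, min(win[2] + m_a + 30, 178))
        }
        d <- runif(1, 0.18, cut - m_d)
      }
      ph <- phi * pi / 180
      # angle measured at O between H and Fe; Fe sits on -x, so H direction
      # makes angle (180 - phi) with +x
      h <- d * c(cos(pi - ph), sin(pi - ph), 0)
      cc <- h * (1 + b_ch / d)
      xyz <- rot_x(az, rbind(h, cc))
      rows[[length(rows) + 1]] <- tibble::tibble(
        role = unname(som$roles[c("H_som", "C_som")]),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }
  }
  dplyr::bind_rows(rows)
}

rot_x <- function(angle, xyz) {
  rot <- matrix(c(1, 0, 0,
                  0, cos(angle), sin(angle),
                  0, -sin(angle), cos(angle)), 3, 3)
  xyz %*% t(rot)
}

# Random proper rotation (QR of a Gaussian matrix) plus random translation.
rigid_motion <- function(atoms, translation_scale = 2) {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_dec) %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- runif(3, -translation_scale, translation_scale)
  xyz <- as.matrix(atoms[c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

#' Published mefenamic acid kinetic parameters
#'
#' The packaged per-temperature Michaelis-Menten parameter table for
#' mefenamic acid hydroxylation: eight temperatures by three metabolites
#' (3'-OH-MF, 4'-OH-MF, 5-OH-MF) for the bacterial mutant BM3 M11, and four
#' temperatures by two metabolites (4'-OH-MF, 5-OH-MF) for human CYP1A2.
#' Vmax in nmol product min^-1 (nmol enzyme)^-1, KM in uM, with the
#' reported standard errors. CYP1A2 does not form 3'-OH-MF, so those
#' entries are absent (not zero).
#'
#' @param enzyme `"BM3 M11"`, `"CYP1A2"`, or `NULL` for both.
#' @return A kinetic parameter tibble (see [read_param_table()]).
#' @examples
#' mefenamic_params("BM3 M11")
#' @export
mefenamic_params <- function(enzyme = NULL) {
  path <- system.file("extdata", "mefenamic_acid_kinetics.csv",
                      package = "p450thermo", mustWork = TRUE)
  tab <- read_param_table(path)
  if (!is.null(enzyme)) tab <- select_enzyme(tab, enzyme)
  tab
}
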