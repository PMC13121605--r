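#' Default synthetic study scenario
#'
#' Parameterizes a simulated IMC study with the structure the pipeline
#' assumes: paired patients with one adjacent-tissue and one tumor ROI each;
#' six cell populations with log-normal marker intensities; a rare activated
#' CD4 population that attracts a KLRF1-like CD8 population (Neyman-Scott
#' offspring placement); a tumor blob that carries CK18/aSMA signal and
#' depletes the attracted pair; channel spillover and Poisson counting
#' noise; and a companion negative-binomial expression experiment carrying
#' the gate markers and Tpex/Tex gene modules.
#'
#' Default magnitudes: 1000 x 1000 px ROIs at 1 um/px; ~1500 cells per ROI
#' rendered as radius-3 disks; the attracted CD8 population is ~6% of CD8
#' cells in adjacent tissue and is reduced to ~1% in tumor tissue (a 6-fold
#' depletion), with additional thinning inside the tumor blob itself; 5
#' paired patients.
#'
#' @param seed Master seed; every simulation draw derives from it.
#' @param roi_px ROI side length in pixels.
#' @param n_patients Number of paired patients.
#' @return An object of class `imc_scenario`.
#' @export
default_scenario <- function(seed = 42, roi_px = 1000, n_patients = 5) {
  markers <- c("CD45", "CD3", "CD19", "CD4", "CD8", "KLRG1", "KLRF1",
               "AICL", "PD1", "CK18", "aSMA", "DNA1")
  lo <- 0.08  # background per-pixel ion-count mean for a negative marker
  profile <- function(...) {
    v <- setNames(rep(lo, length(markers)), markers)
    hi <- c(...)
    v[names(hi)] <- hi
    v
  }
  # per-pixel log-normal intensity means (linear scale) for positive markers
  pop_means <- list(
    CD4_T      = profile(CD45 = 6, CD3 = 8, CD4 = 6, DNA1 = 10),
    CD4_AICL   = profile(CD45 = 6, CD3 = 8, CD4 = 6, KLRG1 = 5, AICL = 6,
                         DNA1 = 10),
    CD8_T      = profile(CD45 = 6, CD3 = 8, CD8 = 6, DNA1 = 10),
    CD8_KLRF1  = profile(CD45 = 6, CD3 = 8, CD8 = 6, KLRG1 = 5, KLRF1 = 6,
                         DNA1 = 10),
    B          = profile(CD45 = 6, CD19 = 7, DNA1 = 10),
    Epithelial = profile(CK18 = 9, DNA1 = 10)
  )
  populations <- tibble(
    name = names(pop_means),
    # B abundance matches the attraction parent so it serves as the
    # independent same-abundance control population for spatial tests
    abundance = c(400, 60, 600, NA, 60, 350),  # NA: placed as offspring
    gate = c("T", "T", "T", "T", "B", "non_immune"),
    lineage = c("CD4", "CD4", "CD8", "CD8", "other", "other")
  )
  marker_params <- purrr::map_dfr(names(pop_means), function(p) {
    tibble(population = p, marker = markers,
           meanlog = log(pop_means[[p]]), sdlog = 0.25)
  })
  spill <- diag(length(markers))
  dimnames(spill) <- list(markers, markers)
  # adjacent-mass spillover, a few percent, fixed
  for (i in seq_len(length(markers) - 1L)) spill[i, i + 1L] <- 0.03
  spill["CD3", "CD4"] <- 0.05
  structure(list(
    seed = seed,
    roi_px = roi_px,
    pixel_size_um = 1,
    cell_radius_px = 3L,
    n_patients = n_patients,
    patient_sdlog = 0.3,
    populations = populations,
    marker_params = marker_params,
    attraction = list(parent = "CD4_AICL", child = "CD8_KLRF1",
                      mean_offspring = 0.65, sigma_att = 10),
    tumor = list(radius_frac = 0.28, ck18_intensity = 12, asma_intensity = 4,
                 depletion = c(CD8_KLRF1 = 0.15, CD4_AICL = 0.4),
                 child_tissue_factor = 1 / 6),
    spillover = spill,
    expression = default_expression_spec(),
    max_place_retries = 10L
  ), class = "imc_scenario")
}

# Negative-binomial expression design: gate genes near-deterministically
# detected where "on" (size 5), structural zeros where lineage-absent, noise
# genes spanning the expression range for control binning, and 15-gene Tpex /
# Tex modules shifted 4-fold in the designated populations.
default_expression_spec <- function(delta = 4) {
  gate_genes <- c("CD3E", "CD3D", "CD3G", "TRAC", "CD8A", "CD8B", "CD4",
                  "TRDC", "TRGC1", "TRGC2", "KLRF1")
  tpex <- sprintf("TPEXM%02d", 1:15)
  tex <- sprintf("TEXM%02d", 1:15)
  noise <- sprintf("BG%03d", 1:150)
  genes <- c(gate_genes, tpex, tex, noise)
  base_noise_means <- exp(seq(log(0.05), log(6), length.out = length(noise)))
  base <- setNames(rep(0, length(genes)), genes)
  base[tpex] <- 2
  base[tex] <- 2
  base[noise] <- base_noise_means
  on <- function(...) {
    v <- base
    hi <- c(...)
    v[names(hi)] <- hi
    v
  }
  t_core <- c(CD3E = 15, CD3D = 10, CD3G = 5, TRAC = 15)
  pop_means <- list(
    CD4_T     = on(t_core, CD4 = 8, KLRF1 = 0.5),
    CD8_T     = on(t_core, CD8A = 10, CD8B = 5, KLRF1 = 0.5),
    CD8_KLRF1 = on(t_core, CD8A = 10, CD8B = 5, KLRF1 = 8,
                   setNames(rep(2 * delta, 15), tpex)),
    CD8_Tex   = on(t_core, CD8A = 10, CD8B = 5, KLRF1 = 0.5,
                   setNames(rep(2 * delta, 15), tex)),
    NK        = on(KLRF1 = 8, CD8A = 0.5),           # CD3E/TRAC structural 0
    gdT       = on(CD3E = 15, CD3D = 10, CD3G = 5, TRDC = 10, TRGC1 = 5,
                   TRGC2 = 3, CD8A = 2)              # TRAC structural 0
  )
  list(
    genes = genes,
    populations = tibble(
      name = names(pop_means),
      n = c(300, 400, 150, 150, 100, 60),
      lineage = c("CD4", "CD8", "CD8", "CD8", "NK", "gdT")
    ),
    means = pop_means,
    size_gate = 5,     # NB dispersion (size) for gate genes
    size_other = 2,    # NB size for module / noise genes
    gate_genes = gate_genes,
    modules = list(Tpex = tpex, Tex = tex),
    delta = delta,
    tpex_population = "CD8_KLRF1",
    tex_population = "CD8_Tex"
  )
}

#' Validate a scenario
#' @param scenario An `imc_scenario`.
#' @return The scenario, invisibly; errors describe the first violation.
#' @export
validate_scenario <- function(scenario) {
  s <- scenario
  stopifnot(inherits(s, "imc_scenario"))
  ab <- s$populations$abundance
  if (any(ab[!is.na(ab)] <= 0)) abort("abundances must be positive")
  dep <- s$tumor$depletion
  if (any(dep < 0 | dep > 1)) abort("depletion factors must lie in [0, 1]")
  if (s$attraction$sigma_att <= 0) abort("sigma_att must be positive")
  if (!s$attraction$parent %in% s$populations$name ||
      !s$attraction$child %in% s$populations$name)
    abort("attraction parent/child must be scenario populations")
  validate_spillover(s$spillover)
  if (!setequal(unique(s$marker_params$population), s$populations$name))
    abort("marker_params must cover exactly the scenario populations")
  invisible(s)
}

#' @export
print.imc_scenario <- function(x, ...) {
  cat(sprintf(paste0("<imc_scenario> %d x %d px ROIs, %d populations, ",
                     "%d paired patients, seed %d\n"),
              x$roi_px, x$roi_px, nrow(x$populations), x$n_patients, x$seed))
  invisible(x)
}

# deterministic substream seed per (scenario, roi); kept below 2^31
roi_seed <- function(scenario, roi_index) {
  (scenario$seed %% 100000L) * 20011L + roi_index * 7919L
}

disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, ]
}

#' Simulate one region of interest
#'
#' Places non-attracted populations by a homogeneous Poisson process and the
#' attracted child population as Gaussian offspring around its parents
#' (Neyman-Scott); thins designated populations inside the tumor blob of
#' tumor-tissue ROIs; enforces non-overlapping cell disks by rejection
#' sampling (cells failing `max_place_retries` re-draws are dropped with a
#' warning, reducing density); draws per-cell log-normal marker means, mixes
#' them through the spillover matrix, and renders Poisson ion-count images.
#'
#' @param scenario An [default_scenario()]-style scenario.
#' @param roi_index Integer >= 1 selecting the deterministic random
#'   substream.
#' @param tissue `"adjacent"` or `"tumor"` (tumor ROIs get the blob).
#' @param patient_id Identity stamped on the truth table.
#' @param abundance_scale Optional named multiplier per population
#'   (between-patient variability; see [simulate_study()]).
#' @param render Render images and masks (`TRUE`), or return the truth table
#'   only, with observed raw means sampled directly from the same counting
#'   model (`FALSE`; much faster, used for large seed sweeps).
#' @param noise Apply Poisson counting noise.
#' @return List with `image` ([roi_image()]; `NULL` when `render = FALSE`),
#'   `mask` (integer label matrix or `NULL`), `cells` (truth tibble: identity,
#'   population, gate, lineage, centroid, area, `in_tumor_truth`,
#'   `true__<marker>` per-pixel means and `raw__<marker>` observed means),
#'   and `tumor` (blob center/radius or `NULL`).
#' @export
simulate_roi <- function(scenario, roi_index = 1L,
                         tissue = c("adjacent", "tumor"),
                         patient_id = "P01", abundance_scale = NULL,
                         render = TRUE, noise = TRUE) {
  tissue <- match.arg(tissue)
  validate_scenario(scenario)
  withr::with_seed(roi_seed(scenario, roi_index), {
    simulate_roi_impl(scenario, roi_index, tissue, patient_id,
                      abundance_scale, render, noise)
  })
}

simulate_roi_impl <- function(scenario, roi_index, tissue, patient_id,
                              abundance_scale, render, noise) {
  s <- scenario
  L <- s$roi_px
  r <- s$cell_radius_px
  pops <- s$populations
  att <- s$attraction
  scale_of <- function(p) {
    if (is.null(abundance_scale) || is.na(abundance_scale[p])) 1
    else abundance_scale[[p]]
  }

  blob <- NULL
  if (tissue == "tumor") {
    rad <- s$tumor$radius_frac * L
    blob <- list(cx = L / 2 + runif(1, -0.1, 0.1) * L,
                 cy = L / 2 + runif(1, -0.1, 0.1) * L, radius = rad)
  }
  in_blob <- function(x, y) {
    if (is.null(blob)) rep(FALSE, length(x))
    else (x - blob$cx)^2 + (y - blob$cy)^2 <= blob$radius^2
  }

  # -- propose positions ------------------------------------------------
  prop <- list()
  for (p in setdiff(pops$name, att$child)) {
    lambda <- pops$abundance[pops$name == p] * scale_of(p)
    n <- rpois(1, lambda)
    if (n == 0) next
    prop[[p]] <- tibble(population = p,
                        x = runif(n, 0, L - 1), y = runif(n, 0, L - 1),
                        parent_x = NA_real_, parent_y = NA_real_)
  }
  parents <- prop[[att$parent]]
  child_rate <- att$mean_offspring * scale_of(att$child)
  if (tissue == "tumor")
    child_rate <- child_rate * s$tumor$child_tissue_factor
  if (!is.null(parents) && nrow(parents) > 0) {
    n_off <- rpois(nrow(parents), child_rate)
    if (sum(n_off) > 0) {
      px <- rep(parents$x, n_off)
      py <- rep(parents$y, n_off)
      prop[[att$child]] <- tibble(
        population = att$child,
        x = pmin(pmax(px + rnorm(sum(n_off), 0, att$sigma_att), 0), L - 1),
        y = pmin(pmax(py + rnorm(sum(n_off), 0, att$sigma_att), 0), L - 1),
        parent_x = px, parent_y = py
      )
    }
  }
  cells <- dplyr::bind_rows(prop)
  if (nrow(cells) == 0L) abort("scenario produced no cells")

  # -- tumor-blob thinning ----------------------------------------------
  if (!is.null(blob)) {
    keep_p <- rep(1, nrow(cells))
    for (p in names(s$tumor$depletion)) {
      hit <- cells$population == p & in_blob(cells$x, cells$y)
      keep_p[hit] <- s$tumor$depletion[[p]]
    }
    cells <- cells[runif(nrow(cells)) < keep_p, , drop = FALSE]
  }

  # -- hard-core placement (non-overlapping disks) ----------------------
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]  # placement order
  min_d2 <- (2 * r + 1)^2
  ax <- numeric(nrow(cells)); ay <- numeric(nrow(cells))
  ok <- logical(nrow(cells))
  n_acc <- 0L
  for (i in seq_len(nrow(cells))) {
    xi <- cells$x[i]; yi <- cells$y[i]
    for (try in seq_len(s$max_place_retries)) {
      clash <- n_acc > 0L &&
        min((ax[seq_len(n_acc)] - xi)^2 + (ay[seq_len(n_acc)] - yi)^2) < min_d2
      if (!clash && xi >= r && xi <= L - 1 - r && yi >= r && yi <= L - 1 - r)
        break
      if (is.na(cells$parent_x[i])) {
        xi <- runif(1, r, L - 1 - r); yi <- runif(1, r, L - 1 - r)
      } else {
        xi <- pmin(pmax(cells$parent_x[i] + rnorm(1, 0, att$sigma_att), r),
                   L - 1 - r)
        yi <- pmin(pmax(cells$parent_y[i] + rnorm(1, 0, att$sigma_att), r),
                   L - 1 - r)
      }
      clash <- TRUE
    }
    if (!clash) {
      n_acc <- n_acc + 1L
      ax[n_acc] <- xi; ay[n_acc] <- yi; ok[i] <- TRUE
      cells$x[i] <- xi; cells$y[i] <- yi
    }
  }
  if (!all(ok))
    warn(sprintf("dropped %d cell(s) after %d placement retries (density reduced)",
                 sum(!ok), s$max_place_retries))
  cells <- cells[ok, , drop = FALSE]

  # integer disk centers
  cells$x <- round(cells$x); cells$y <- round(cells$y)

  # -- per-cell marker means and spillover mixing -----------------------
  markers <- rownames(s$spillover)
  mp <- s$marker_params
  true_means <- matrix(0, nrow(cells), length(markers),
                       dimnames = list(NULL, markers))
  for (p in unique(cells$population)) {
    rows <- which(cells$population == p)
    par <- mp[mp$population == p, ]
    par <- par[match(markers, par$marker), ]
    true_means[rows, ] <- matrix(
      rlnorm(length(rows) * length(markers),
             meanlog = rep(par$meanlog, each = length(rows)),
             sdlog = rep(par$sdlog, each = length(rows))),
      nrow = length(rows)
    )
  }
  mixed_means <- true_means %*% s$spillover

  off <- disk_offsets(r)
  area <- nrow(off)
  truth <- tibble(
    cell_id = seq_len(nrow(cells)),
    roi_id = sprintf("ROI%03d", roi_index),
    patient_id = patient_id,
    tissue_type = tissue,
    population = cells$population,
    gate = pops$gate[match(cells$population, pops$name)],
    lineage = pops$lineage[match(cells$population, pops$name)],
    centroid_x = cells$x, centroid_y = cells$y,
    area_px = area,
    in_tumor_truth = in_blob(cells$x, cells$y)
  )
  for (m in markers) truth[[paste0("true__", m)]] <- true_means[, m]

  image <- NULL; mask <- NULL
  if (render) {
    n <- nrow(cells)
    mask <- matrix(0L, L, L)
    px_row <- rep(cells$y + 1L, each = area) + rep(off$dy, n)   # 1-based rows
    px_col <- rep(cells$x + 1L, each = area) + rep(off$dx, n)
    px_lab <- rep(seq_len(n), each = area)
    mask[cbind(px_row, px_col)] <- px_lab
    arr <- array(0, dim = c(L, L, length(markers)),
                 dimnames = list(NULL, NULL, markers))
    blob_field <- NULL
    if (!is.null(blob)) {
      xs <- matrix(rep(0:(L - 1), each = L), L, L)   # column index (x)
      ys <- matrix(rep(0:(L - 1), times = L), L, L)  # row index (y)
      blob_field <- (xs - blob$cx)^2 + (ys - blob$cy)^2 <= blob$radius^2
    }
    for (k in seq_along(markers)) {
      ch <- matrix(0, L, L)
      ch[cbind(px_row, px_col)] <- mixed_means[px_lab, k]
      if (!is.null(blob_field)) {
        extra <- switch(markers[k], CK18 = s$tumor$ck18_intensity,
                        aSMA = s$tumor$asma_intensity, 0)
        if (extra > 0) ch <- ch + extra * blob_field
      }
      arr[, , k] <- ch
    }
    if (noise) arr[] <- rpois(length(arr), arr)
    image <- roi_image(arr, markers, roi_id = sprintf("ROI%03d", roi_index),
                       pixel_size_um = s$pixel_size_um)
    for (m in markers) {
      v <- image$pixels[, , m][mask > 0]
      truth[[paste0("raw__", m)]] <-
        as.vector(rowsum(v, mask[mask > 0])) / area
    }
  } else {
    for (j in seq_along(markers)) {
      mu <- mixed_means[, j] * area
      obs <- if (noise) rpois(length(mu), mu) else mu
      truth[[paste0("raw__", markers[j])]] <- obs / area
    }
  }
  list(image = image, mask = mask, cells = truth, tumor = blob)
}

#' Simulate a full paired study
#'
#' One adjacent and one tumor ROI per patient, with a shared log-normal
#' between-patient abundance multiplier (so tissue contrasts are paired).
#'
#' @inheritParams simulate_roi
#' @return Combined truth cell table across all ROIs (plus images/masks in
#'   the `rois` attribute when `render = TRUE`).
#' @export
simulate_study <- function(scenario, render = FALSE, noise = TRUE) {
  validate_scenario(scenario)
  pats <- sprintf("P%02d", seq_len(scenario$n_patients))
  pat_scale <- withr::with_seed(scenario$seed, {
    matrix(exp(rnorm(length(pats) * nrow(scenario$populations),
                     0, scenario$patient_sdlog)),
           nrow = length(pats),
           dimnames = list(pats, scenario$populations$name))
  })
  idx <- 0L
  rois <- list()
  tabs <- list()
  for (p in pats) {
    for (tt in c("adjacent", "tumor")) {
      idx <- idx + 1L
      sim <- simulate_roi(scenario, roi_index = idx, tissue = tt,
                          patient_id = p, abundance_scale = pat_scale[p, ],
                          render = render, noise = noise)
      sim$cells$roi_id <- sprintf("%s_%s", p, tt)
      tabs[[idx]] <- sim$cells
      if (render) rois[[sprintf("%s_%s", p, tt)]] <- sim
    }
  }
  out <- dplyr::bind_rows(tabs)
  if (render) attr(out, "rois") <- rois
  out
}

#' Simulate an ROI containing only a tumor blob (mask benchmarking)
#'
#' A single bright CK18/aSMA blob over Poisson background noise, at a given
#' signal-to-noise ratio (blob mean intensity over the background noise sd),
#' with the ground-truth blob mask returned.
#'
#' @param size ROI side (px).
#' @param radius Blob radius (px).
#' @param snr Signal-to-noise ratio, `signal / sqrt(background_mean)`.
#' @param background_mean Poisson background mean.
#' @param seed Seed.
#' @return List with `image` ([roi_image()] with CK18 and aSMA channels) and
#'   `truth` (logical blob mask).
#' @export
simulate_mask_roi <- function(size = 384, radius = 55, snr = 5,
                              background_mean = 4, seed = 1) {
  withr::with_seed(seed, {
    cx <- runif(1, 0.35, 0.65) * size
    cy <- runif(1, 0.35, 0.65) * size
    xs <- matrix(rep(0:(size - 1), each = size), size, size)
    ys <- matrix(rep(0:(size - 1), times = size), size, size)
    truth <- (xs - cx)^2 + (ys - cy)^2 <= radius^2
    signal <- snr * sqrt(background_mean)
    ck18 <- matrix(rpois(size^2, background_mean + signal * truth), size, size)
    asma <- matrix(rpois(size^2, background_mean / 2 +
                           (signal / 3) * truth), size, size)
    img <- roi_image(array(c(ck18, asma), dim = c(size, size, 2)),
                     channels = c("CK18", "aSMA"), roi_id = "mask_sim")
    list(image = img, truth = truth)
  })
}

#' Simulate a cell-by-gene expression experiment
#'
#' Negative-binomial counts with population-specific means. Gate genes are
#' on/off consistently with each population's lineage (NK cells carry
#' structural zeros for CD3E/TRAC); Tpex/Tex module genes are shifted
#' `delta`-fold in the designated populations; KLRF1 is 16-fold higher in
#' the KLRF1-high CD8 population than in other CD8 populations.
#'
#' @param scenario An `imc_scenario` (its `expression` component is used).
#' @param seed Seed; defaults to the scenario seed.
#' @return List with `counts` (cells x genes integer matrix), `meta`
#'   (tibble: `cell_id`, `population`, `lineage`), and `modules` (named list
#'   of ground-truth module gene sets).
#' @export
simulate_expression <- function(scenario, seed = scenario$seed) {
  ex <- scenario$expression
  withr::with_seed(seed, {
    blocks <- lapply(seq_len(nrow(ex$populations)), function(i) {
      p <- ex$populations$name[i]
      n <- ex$populations$n[i]
      mu <- ex$means[[p]]
      size <- ifelse(names(mu) %in% ex$gate_genes, ex$size_gate,
                     ex$size_other)
      m <- matrix(0L, n, length(mu))
      pos <- mu > 0
      m[, pos] <- rnbinom(n * sum(pos),
                          mu = rep(mu[pos], each = n),
                          size = rep(size[pos], each = n))
      m
    })
    counts <- do.call(rbind, blocks)
    colnames(counts) <- ex$genes
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
    meta <- tibble(
      cell_id = rownames(counts),
      population = rep(ex$populations$name, ex$populations$n),
      lineage = rep(ex$populations$lineage, ex$populations$n)
    )
    list(counts = counts, meta = meta, modules = ex$modules)
  })
}

#' Simulate paired per-sample cluster frequencies
#'
#' Frequency-level model of the depleted-population contrast: each patient
#' carries a shared log-normal effect; each sample adds independent
#' log-normal noise; the observed cluster count is binomial given the
#' sample's parent-cell count. Defaults encode a 6% (adjacent) vs 1% (tumor)
#' cluster fraction.
#'
#' @param n_patients Paired patients.
#' @param frac_adjacent,frac_tumor Expected cluster fraction by tissue.
#' @param sdlog_patient,sdlog_sample Between-patient / within-sample
#'   log-normal variability of the fraction.
#' @param cells_per_sample Expected parent-cell count per sample (Poisson).
#' @param seed Seed.
#' @return Tibble: `patient_id`, `tissue_type`, `n_parent`, `n`, `fraction`.
#' @export
simulate_cluster_frequencies <- function(n_patients = 10,
                                         frac_adjacent = 0.06,
                                         frac_tumor = 0.01,
                                         sdlog_patient = 0.4,
                                         sdlog_sample = 0.25,
                                         cells_per_sample = 600,
                                         seed = 1) {
  withr::with_seed(seed, {
    pat_eff <- exp(rnorm(n_patients, 0, sdlog_patient))
    out <- purrr::map_dfr(seq_len(n_patients), function(i) {
      purrr::map_dfr(c(adjacent = frac_adjacent, tumor = frac_tumor),
                     function(f0) {
        f <- min(f0 * pat_eff[i] * exp(rnorm(1, 0, sdlog_sample)), 0.5)
        n_par <- rpois(1, cells_per_sample)
        n_cl <- rbinom(1, n_par, f)
        tibble(n_parent = n_par, n = n_cl,
               fraction = ifelse(n_par > 0, n_cl / n_par, NA_real_))
      }, .id = "tissue_type") |>
        dplyr::mutate(patient_id = sprintf("P%02d", i), .before = 1)
    })
    out
  })
}
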