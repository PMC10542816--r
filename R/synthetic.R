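#' Specification of a synthetic single-cell experiment
#'
#' Bundles everything the generator needs: the cell-type catalogue and
#' per-condition composition, per-gene negative-binomial parameters
#' (mean/dispersion with variance mu + alpha*mu^2), marker programs, the
#' per-cell depth model (log-normal total UMI, multinomial allocation),
#' mitochondrial routing, an optional latent differentiation axis, and
#' optional condition-specific gene-set mean shifts.
#'
#' @param n_cells_per_condition Positive integer (0 allowed: empty matrix).
#' @param cell_types Character vector of type names.
#' @param composition Types x conditions matrix of probabilities; each column
#'   sums to 1 within 1e-9.
#' @param conditions Character vector of condition names (matrix columns).
#' @param gene_ids Character vector of gene ids.
#' @param baseline_mean Positive per-gene relative expression at unit depth.
#' @param nb_dispersion Non-negative per-gene NB dispersion alpha
#'   (variance mu + alpha mu^2; 0 degenerates to Poisson).
#' @param marker_map Named list: type -> list(genes=..., lfc=...) giving the
#'   marker genes and their log2 fold-change over baseline in that type.
#' @param depth Named list per condition: list(meanlog=, sdlog=) of the
#'   log-normal per-cell total-UMI law.
#' @param mito_genes Gene ids receiving the mitochondrial count fraction.
#' @param mito_fraction Mean per-cell fraction of counts routed to
#'   `mito_genes`.
#' @param mito_concentration Beta concentration of the per-cell jitter around
#'   `mito_fraction` (shape1+shape2); larger = tighter.
#' @param latent_axis Optional list(cell_types=, genes=, loadings=, shift=):
#'   affected types get a latent coordinate z ~ N(0,1) (N(shift,1) in the
#'   last condition); axis gene means are multiplied by 2^(loading*z).
#' @param geneset_shifts Optional list of list(set=, condition=, lfc=):
#'   log2 mean fold shift applied to the named gene set in one condition.
#' @param gene_sets Optional [gene_set_collection] shipped with the spec
#'   (marker reference for annotation plus any shifted signature sets).
#' @param n_tags Number of hashtags per condition (cells are assigned a true
#'   tag uniformly).
#' @param name Preset name or free label.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells_per_condition, cell_types, composition,
                           conditions = colnames(composition), gene_ids,
                           baseline_mean, nb_dispersion, marker_map = list(),
                           depth, mito_genes = character(),
                           mito_fraction = 0.04, mito_concentration = 50,
                           latent_axis = NULL, geneset_shifts = list(),
                           gene_sets = NULL, n_tags = 3L, name = "custom") {
  n_cells_per_condition <- as.integer(n_cells_per_condition)
  if (is.na(n_cells_per_condition) || n_cells_per_condition < 0L)
    cs_stop("n_cells_per_condition must be a non-negative integer")
  composition <- as.matrix(composition)
  if (nrow(composition) != length(cell_types))
    cs_stop("composition rows != cell_types")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(ncol(composition)))
  if (ncol(composition) != length(conditions))
    cs_stop("composition columns != conditions")
  if (any(abs(colSums(composition) - 1) > 1e-9))
    cs_stop("each composition column must sum to 1 within 1e-9")
  if (any(composition < 0)) cs_stop("composition entries must be >= 0")
  if (length(baseline_mean) != length(gene_ids) ||
      length(nb_dispersion) != length(gene_ids))
    cs_stop("baseline_mean and nb_dispersion must be per-gene")
  if (any(baseline_mean <= 0)) cs_stop("baseline_mean must be > 0")
  if (any(nb_dispersion < 0)) cs_stop("nb_dispersion must be >= 0")
  for (ty in names(marker_map)) {
    if (!ty %in% cell_types) cs_stop("marker_map type '%s' not a cell type", ty)
    bad <- setdiff(marker_map[[ty]]$genes, gene_ids)
    if (length(bad)) cs_stop("marker gene '%s' not in gene_ids", bad[1])
  }
  if (length(bad <- setdiff(mito_genes, gene_ids)))
    cs_stop("mito gene '%s' not in gene_ids", bad[1])
  if (!all(names(depth) == conditions)) depth <- depth[conditions]
  rownames(composition) <- cell_types; colnames(composition) <- conditions
  structure(list(n_cells_per_condition = n_cells_per_condition,
                 cell_types = cell_types, composition = composition,
                 conditions = conditions, gene_ids = gene_ids,
                 baseline_mean = setNames(baseline_mean, gene_ids),
                 nb_dispersion = setNames(nb_dispersion, gene_ids),
                 marker_map = marker_map, depth = depth,
                 mito_genes = mito_genes, mito_fraction = mito_fraction,
                 mito_concentration = mito_concentration,
                 latent_axis = latent_axis, geneset_shifts = geneset_shifts,
                 gene_sets = gene_sets, n_tags = as.integer(n_tags),
                 name = name),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec '%s': %d types x %d conditions, %d genes, %d cells/condition\n",
              x$name, length(x$cell_types), length(x$conditions),
              length(x$gene_ids), x$n_cells_per_condition))
  invisible(x)
}

#' True odds ratios implied by a composition matrix
#'
#' For each cell type, the cross-product odds ratio of (type vs rest) between
#' the second and first condition columns.
#'
#' @param spec A `synthetic_spec` (or a types x 2 composition matrix).
#' @return Named numeric vector of odds ratios.
#' @export
true_odds_ratios <- function(spec) {
  comp <- if (inherits(spec, "synthetic_spec")) spec$composition else spec
  p <- comp[, 1]; q <- comp[, 2]
  (q / (1 - q)) / (p / (1 - p))
}

# Shift a baseline composition so listed types reach a target odds ratio,
# other non-absorber types stay exactly equal (true OR 1), and `absorb`
# types take up the slack proportionally to their baseline share.
shift_composition <- function(p, or, absorb) {
  q <- p
  for (ty in names(or)) {
    odds <- or[[ty]] * p[[ty]] / (1 - p[[ty]])
    q[[ty]] <- odds / (1 + odds)
  }
  delta <- sum(q[names(or)]) - sum(p[names(or)])
  q[absorb] <- p[absorb] - delta * p[absorb] / sum(p[absorb])
  if (any(q <= 0)) cs_stop("composition shift drives a type below zero")
  stopifnot(abs(sum(q) - 1) < 1e-12)
  q
}

# deterministic per-gene parameter draws shared by the presets
preset_genes <- function(n_genes, marker_genes, mito_genes, seed) {
  filler_n <- n_genes - length(marker_genes) - length(mito_genes)
  gene_ids <- c(marker_genes, mito_genes,
                sprintf("gene%04d", seq_len(filler_n)))
  with_seed(seed, {
    base <- setNames(numeric(n_genes), gene_ids)
    base[marker_genes] <- runif(length(marker_genes), 0.1, 0.25)
    base[mito_genes] <- runif(length(mito_genes), 0.5, 1.5)
    base[startsWith(gene_ids, "gene")] <- rlnorm(filler_n, log(0.25), 1.2)
    disp <- setNames(runif(n_genes, 0.4, 1.2), gene_ids)
    disp[marker_genes] <- 0.3
    list(gene_ids = gene_ids, baseline_mean = base, nb_dispersion = disp)
  })
}

#' Built-in study presets
#'
#' `crypt10`: 10 intestinal crypt cell types (young/old) with an Lgr5+ stem
#' type, a secretory-precursor program forming a latent differentiation axis
#' (1 SD old-condition shift along it), old-enriched secretory types, and an
#' antigen-presentation-like gene set upshifted in the old condition.
#' `immune9`: 9 lamina-propria immune types (young/old) with old-enriched
#' ILC2-like (true OR 3 at 5% baseline) and cytotoxic-T-like (true OR 5)
#' types and a depleted naive-T-like absorber; all other types have true
#' OR exactly 1. `organoid7`: 7 organoid epithelial types (control/IFNg)
#' with treated-condition secretory (Goblet OR 3, enteroendocrine OR 2)
#' enrichment.
#'
#' @param name One of `"crypt10"`, `"immune9"`, `"organoid7"`.
#' @return A [synthetic_spec].
#' @export
make_preset <- function(name) {
  switch(name,
         crypt10 = preset_crypt10(),
         immune9 = preset_immune9(),
         organoid7 = preset_organoid7(),
         cs_stop("unknown preset '%s' (known: crypt10, immune9, organoid7)",
                 name))
}

marker_block <- function(types, named) {
  mm <- list()
  for (ty in types) {
    extra <- sprintf("%s.mk%d", abbreviate(ty, 6), seq_len(4))
    mm[[ty]] <- list(genes = c(named[[ty]], extra), lfc = 3)
  }
  mm
}

preset_crypt10 <- function() {
  types <- c("Stem", "TA", "SecretoryPrecursor", "EnterocyteProgenitor",
             "EnterocyteImmature", "EnterocyteMature", "Goblet", "Paneth",
             "Tuft", "Enteroendocrine")
  named <- list(Stem = c("Lgr5", "Olfm4"), TA = c("Mki67", "Top2a"),
                SecretoryPrecursor = c("Dll1", "Atoh1"),
                EnterocyteProgenitor = c("Ckmt1", "Sis"),
                EnterocyteImmature = c("Alpi", "Apoa1"),
                EnterocyteMature = c("Fabp1", "Slc5a1"),
                Goblet = c("Muc2", "Tff3"), Paneth = c("Lyz1", "Defa24"),
                Tuft = c("Dclk1", "Trpm5"),
                Enteroendocrine = c("Chga", "Chgb"))
  mm <- marker_block(types, named)
  young <- c(Stem = 0.14, TA = 0.18, SecretoryPrecursor = 0.06,
             EnterocyteProgenitor = 0.15, EnterocyteImmature = 0.15,
             EnterocyteMature = 0.12, Goblet = 0.08, Paneth = 0.06,
             Tuft = 0.03, Enteroendocrine = 0.03)
  old <- shift_composition(young,
                           c(Goblet = 2, Enteroendocrine = 2, Tuft = 1.5,
                             SecretoryPrecursor = 2),
                           absorb = c("Stem", "TA"))
  marker_genes <- unique(unlist(lapply(mm, `[[`, "genes")))
  mito <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp6", "Cytb",
                          "Nd4", "Rnr2"))
  axis_genes <- sprintf("axis.g%02d", seq_len(60))
  app_genes <- sprintf("app.g%02d", seq_len(40))
  gp <- preset_genes(1200 - length(axis_genes) - length(app_genes),
                     marker_genes, mito, seed = 20101L)
  gene_ids <- c(gp$gene_ids, axis_genes, app_genes)
  base <- c(gp$baseline_mean,
            setNames(rep(0.3, length(axis_genes)), axis_genes),
            setNames(rep(0.3, length(app_genes)), app_genes))
  disp <- c(gp$nb_dispersion,
            setNames(rep(0.3, length(axis_genes)), axis_genes),
            setNames(rep(0.4, length(app_genes)), app_genes))
  loadings <- with_seed(20102L, {
    sample(c(-1, 1), 60, replace = TRUE) * runif(60, 0.4, 1.0)
  })
  sets <- c(lapply(mm, `[[`, "genes"),
            list(APP = app_genes, SecretoryAxis = axis_genes))
  synthetic_spec(
    n_cells_per_condition = 1500L, cell_types = types,
    composition = cbind(young = young, old = old[types]),
    conditions = c("young", "old"), gene_ids = gene_ids,
    baseline_mean = base[gene_ids], nb_dispersion = disp[gene_ids],
    marker_map = mm,
    depth = list(young = list(meanlog = log(2200), sdlog = 0.40),
                 old = list(meanlog = log(1800), sdlog = 0.40)),
    mito_genes = mito, mito_fraction = 0.04, mito_concentration = 50,
    latent_axis = list(cell_types = c("Stem", "TA", "SecretoryPrecursor"),
                       genes = axis_genes, loadings = loadings, shift = 1),
    geneset_shifts = list(list(set = "APP", condition = "old", lfc = 0.75)),
    gene_sets = gene_set_collection(sets), n_tags = 3L, name = "crypt10")
}

preset_immune9 <- function() {
  types <- c("ILC2", "CytotoxicT", "NaiveT", "BCell", "Macrophage", "DC",
             "NK", "Treg", "Plasma")
  named <- list(ILC2 = c("Gata3", "Il13"), CytotoxicT = c("Cd8a", "Gzmb"),
                NaiveT = c("Ccr7", "Sell"), BCell = c("Cd19", "Ms4a1"),
                Macrophage = c("Adgre1", "Csf1r"), DC = c("Itgax", "Flt3"),
                NK = c("Ncr1", "Klrb1c"), Treg = c("Foxp3", "Il2ra"),
                Plasma = c("Jchain", "Xbp1"))
  mm <- marker_block(types, named)
  young <- c(ILC2 = 0.05, CytotoxicT = 0.03, NaiveT = 0.25, BCell = 0.20,
             Macrophage = 0.12, DC = 0.08, NK = 0.10, Treg = 0.07,
             Plasma = 0.10)
  old <- shift_composition(young, c(ILC2 = 3, CytotoxicT = 5),
                           absorb = "NaiveT")
  marker_genes <- unique(unlist(lapply(mm, `[[`, "genes")))
  mito <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp6", "Cytb",
                          "Nd4", "Rnr2"))
  gp <- preset_genes(2000L, marker_genes, mito, seed = 20201L)
  synthetic_spec(
    n_cells_per_condition = 4500L, cell_types = types,
    composition = cbind(young = young, old = old[types]),
    conditions = c("young", "old"), gene_ids = gp$gene_ids,
    baseline_mean = gp$baseline_mean, nb_dispersion = gp$nb_dispersion,
    marker_map = mm,
    depth = list(young = list(meanlog = log(1500), sdlog = 0.45),
                 old = list(meanlog = log(1250), sdlog = 0.45)),
    mito_genes = mito, mito_fraction = 0.04, mito_concentration = 50,
    gene_sets = gene_set_collection(lapply(mm, `[[`, "genes")),
    n_tags = 3L, name = "immune9")
}

preset_organoid7 <- function() {
  types <- c("Stem", "Progenitor", "Enterocyte", "Goblet", "Paneth",
             "Enteroendocrine", "Tuft")
  named <- list(Stem = c("Lgr5", "Olfm4"), Progenitor = c("Mki67", "Top2a"),
                Enterocyte = c("Alpi", "Fabp1"), Goblet = c("Muc2", "Tff3"),
                Paneth = c("Lyz1", "Defa24"),
                Enteroendocrine = c("Chga", "Chgb"),
                Tuft = c("Dclk1", "Trpm5"))
  mm <- marker_block(types, named)
  ctrl <- c(Stem = 0.20, Progenitor = 0.22, Enterocyte = 0.30, Goblet = 0.10,
            Paneth = 0.08, Enteroendocrine = 0.05, Tuft = 0.05)
  trt <- shift_composition(ctrl, c(Goblet = 3, Enteroendocrine = 2),
                           absorb = "Enterocyte")
  marker_genes <- unique(unlist(lapply(mm, `[[`, "genes")))
  mito <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp6", "Cytb",
                          "Nd4", "Rnr2"))
  gp <- preset_genes(1500L, marker_genes, mito, seed = 20301L)
  synthetic_spec(
    n_cells_per_condition = 2000L, cell_types = types,
    composition = cbind(control = ctrl, IFNg = trt[types]),
    conditions = c("control", "IFNg"), gene_ids = gp$gene_ids,
    baseline_mean = gp$baseline_mean, nb_dispersion = gp$nb_dispersion,
    marker_map = mm,
    depth = list(control = list(meanlog = log(2000), sdlog = 0.50),
                 IFNg = list(meanlog = log(2000), sdlog = 0.50)),
    mito_genes = mito, mito_fraction = 0.06, mito_concentration = 30,
    gene_sets = gene_set_collection(lapply(mm, `[[`, "genes")),
    n_tags = 3L, name = "organoid7")
}

#' Draw ground-truth cell identities (composition layer only)
#'
#' Samples, for each condition, `n_cells_per_condition` cell types from the
#' spec's composition vector, plus the latent axis coordinate for affected
#' types. This is the identity layer of [simulate_counts]; it is exposed so
#' composition-recovery studies need not generate expression.
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer seed.
#' @return A data.frame (class `ground_truth_cells`) with columns `cell_id`,
#'   `condition`, `sample`, `cell_type`, `latent`.
#' @export
simulate_cell_types <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    out <- lapply(spec$conditions, function(cond) {
      n <- spec$n_cells_per_condition
      if (n == 0L) {
        return(data.frame(cell_id = character(), condition = character(),
                          sample = character(), cell_type = character(),
                          latent = numeric(), stringsAsFactors = FALSE))
      }
      ty <- sample(spec$cell_types, n, replace = TRUE,
                   prob = spec$composition[, cond])
      z <- rep(NA_real_, n)
      la <- spec$latent_axis
      if (!is.null(la)) {
        aff <- ty %in% la$cell_types
        shift <- if (cond == spec$conditions[length(spec$conditions)])
          la$shift else 0
        z[aff] <- rnorm(sum(aff), mean = shift, sd = 1)
      }
      data.frame(cell_id = sprintf("%s-%05d", cond, seq_len(n)),
                 condition = cond, sample = cond, cell_type = ty,
                 latent = z, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    class(out) <- c("ground_truth_cells", "data.frame")
    out
  })
}

#' Simulate a UMI matrix with ground truth
#'
#' Per cell: a type is drawn from the condition's composition; a total depth
#' from the condition's log-normal law; per-gene relative rates are the
#' spec's baseline means, times 2^lfc for the type's markers, times latent
#' axis and gene-set shift factors, each perturbed by a mean-1 Gamma with
#' variance `nb_dispersion` (so per-gene counts at fixed depth follow a
#' negative binomial with variance mu + alpha*mu^2); a Beta-jittered
#' fraction of the depth is routed to the mitochondrial genes; counts are
#' allocated multinomially.
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer seed; identical spec+seed gives identical output.
#' @return A list with elements `matrix` (a [umi_matrix]) and `truth`
#'   (list: `cells` ground-truth data.frame, `odds_ratios`, `markers`).
#' @export
simulate_counts <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cells <- simulate_cell_types(spec, seed)
  n_genes <- length(spec$gene_ids)
  gene_index <- setNames(seq_len(n_genes), spec$gene_ids)
  mito_idx <- gene_index[spec$mito_genes]
  # per-(type, condition) deterministic mean vectors
  mean_for <- function(type, cond) {
    mu <- spec$baseline_mean
    mk <- spec$marker_map[[type]]
    if (!is.null(mk)) mu[mk$genes] <- mu[mk$genes] * 2^mk$lfc
    for (gs in spec$geneset_shifts) {
      if (gs$condition == cond) {
        genes <- if (!is.null(spec$gene_sets) && gs$set %in% names(spec$gene_sets))
          spec$gene_sets[[gs$set]] else gs$set
        mu[genes] <- mu[genes] * 2^gs$lfc
      }
    }
    mu
  }
  mu_table <- list()
  for (cond in spec$conditions)
    for (ty in spec$cell_types)
      mu_table[[paste(ty, cond, sep = "\r")]] <- mean_for(ty, cond)
  la <- spec$latent_axis
  axis_idx <- if (!is.null(la)) gene_index[la$genes]
  alpha <- spec$nb_dispersion
  pos_a <- alpha > 0
  truth_or <- true_odds_ratios(spec)
  markers <- lapply(spec$marker_map, `[[`, "genes")

  counts <- with_seed(seed + 1L, {
    n_cells <- nrow(cells)
    if (n_cells == 0L) {
      Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(0L, n_genes))
    } else {
      depth <- numeric(n_cells)
      for (cond in spec$conditions) {
        idx <- which(cells$condition == cond)
        dp <- spec$depth[[cond]]
        depth[idx] <- pmax(1, round(rlnorm(length(idx), dp$meanlog, dp$sdlog)))
      }
      mf <- spec$mito_fraction; mc <- spec$mito_concentration
      mito_frac <- if (length(mito_idx))
        rbeta(n_cells, mf * mc, (1 - mf) * mc) else rep(0, n_cells)
      ilist <- vector("list", n_cells)
      xlist <- vector("list", n_cells)
      for (i in seq_len(n_cells)) {
        mu <- mu_table[[paste(cells$cell_type[i], cells$condition[i],
                              sep = "\r")]]
        if (!is.null(la) && !is.na(cells$latent[i]))
          mu[axis_idx] <- mu[axis_idx] * 2^(la$loadings * cells$latent[i])
        w <- mu
        w[pos_a] <- w[pos_a] * rgamma(sum(pos_a), shape = 1 / alpha[pos_a],
                                      rate = 1 / alpha[pos_a])
        if (length(mito_idx)) {
          sm <- sum(w[mito_idx]); so <- sum(w[-mito_idx])
          w[mito_idx] <- mito_frac[i] * w[mito_idx] / sm
          w[-mito_idx] <- (1 - mito_frac[i]) * w[-mito_idx] / so
        }
        ct <- rmultinom(1, depth[i], w)[, 1]
        nz <- which(ct > 0)
        ilist[[i]] <- nz
        xlist[[i]] <- ct[nz]
      }
      lens <- lengths(ilist)
      Matrix::sparseMatrix(i = rep.int(seq_len(n_cells), lens),
                           j = unlist(ilist), x = unlist(xlist),
                           dims = c(n_cells, n_genes))
    }
  })
  m <- umi_matrix(counts, cell_ids = cells$cell_id, gene_ids = spec$gene_ids,
                  mito_flags = spec$gene_ids %in% spec$mito_genes,
                  sample_label = if (nrow(cells)) cells$sample else character(0),
                  condition_label = if (nrow(cells)) cells$condition else character(0))
  list(matrix = m,
       truth = list(cells = cells, odds_ratios = truth_or, markers = markers))
}

#' Simulate per-cell hashtag read counts
#'
#' Singlet cells put (1 - background_fraction) of their hashtag reads on
#' their true tag, the rest spread uniformly over the other tags; doublets
#' split the signal evenly over two tags; low-signal cells get fewer than 10
#' total reads. Truth gains `hashtag`, `hashtag2`, `doublet`, `low_signal`.
#'
#' @param truth A ground-truth cells data.frame (from [simulate_cell_types]
#'   or `simulate_counts()$truth$cells`).
#' @param n_tags Number of tags (>= 1).
#' @param reads_per_cell list(meanlog=, sdlog=) log-normal total hashtag
#'   reads for non-low-signal cells.
#' @param doublet_rate,low_signal_rate,background_fraction Fractions in
#'   [0,1]; `background_fraction >= 0.5` is rejected (signal unidentifiable).
#' @param seed Integer seed.
#' @return list(hashtags = `hashtag_counts`, truth = updated data.frame).
#' @export
simulate_hashtags <- function(truth, n_tags = 3L,
                              reads_per_cell = list(meanlog = log(200),
                                                    sdlog = 0.5),
                              doublet_rate = 0.05, low_signal_rate = 0.02,
                              background_fraction = 0.02, seed = 1L) {
  check_fraction(doublet_rate, "doublet_rate")
  check_fraction(low_signal_rate, "low_signal_rate")
  check_fraction(background_fraction, "background_fraction")
  if (background_fraction >= 0.5)
    cs_stop("background_fraction >= 0.5: hashtag signal not identifiable")
  n_tags <- as.integer(n_tags)
  if (n_tags < 1L) cs_stop("n_tags must be >= 1")
  n <- nrow(truth)
  tags <- paste0("tag", seq_len(n_tags))
  with_seed(seed, {
    true_tag <- sample(n_tags, n, replace = TRUE)
    doublet <- runif(n) < doublet_rate
    low <- runif(n) < low_signal_rate
    second <- rep(NA_integer_, n)
    if (n_tags >= 2L) {
      di <- which(doublet)
      second[di] <- vapply(true_tag[di], function(t1)
        sample(setdiff(seq_len(n_tags), t1), 1L), 1L)
    } else doublet[] <- FALSE
    total <- pmax(10, round(rlnorm(n, reads_per_cell$meanlog,
                                   reads_per_cell$sdlog)))
    total[low] <- sample(0:9, sum(low), replace = TRUE)
    counts <- matrix(0L, n, n_tags, dimnames = list(truth$cell_id, tags))
    for (i in seq_len(n)) {
      if (total[i] == 0) next
      if (n_tags == 1L) {
        p <- 1
      } else if (doublet[i]) {
        sig <- c(true_tag[i], second[i])
        p <- rep(if (n_tags > 2L) background_fraction / (n_tags - 2L) else 0,
                 n_tags)
        p[sig] <- if (n_tags > 2L) (1 - background_fraction) / 2 else 0.5
      } else {
        p <- rep(background_fraction / (n_tags - 1L), n_tags)
        p[true_tag[i]] <- 1 - background_fraction
      }
      counts[i, ] <- rmultinom(1, total[i], p)[, 1]
    }
    truth$hashtag <- tags[true_tag]
    truth$hashtag2 <- ifelse(is.na(second), NA_character_, tags[second])
    truth$doublet <- doublet
    truth$low_signal <- low
    list(hashtags = hashtag_counts(counts), truth = truth)
  })
}

#' Hashtag count table
#'
#' @param counts Cells x tags non-negative integer matrix with unique
#'   rownames (cell ids) and colnames (tag names).
#' @return Object of class `hashtag_counts`.
#' @export
hashtag_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    cs_stop("hashtag counts need unique cell-id rownames")
  if (ncol(counts) < 1L) cs_stop("need at least one tag")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("tag", seq_len(ncol(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    cs_stop("hashtag counts must be non-negative integers")
  structure(counts, class = c("hashtag_counts", class(counts)))
}

#' Write a simulated dataset as plain-text files
#'
#' Writes the 10x triplet, `hashtags.tsv`, `truth.tsv` and `spec.yaml` under
#' `dir`.
#'
#' @param sim Result of [simulate_counts].
#' @param hash Optional result of [simulate_hashtags].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, hash = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_10x_triplet(sim$matrix, dir)
  truth <- if (!is.null(hash)) hash$truth else sim$truth$cells
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(hash)) {
    ht <- data.frame(cell_id = rownames(hash$hashtags),
                     as.data.frame(unclass(hash$hashtags)),
                     check.names = FALSE)
    write.table(ht, file.path(dir, "hashtags.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  or <- sim$truth$odds_ratios
  yaml::write_yaml(list(odds_ratios = as.list(or)),
                   file.path(dir, "spec.yaml"))
  invisible(dir)
}
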