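#' Design for a synthetic cell-line panel
#'
#' Captures the conditions the generator emulates: a breast-cancer-like
#' panel with transcriptional-subtype structure, planted response-associated
#' features at chosen omic levels, and GI50s consistent with the planted
#' effects. Defaults mirror a mid-size panel: 48 lines with response data,
#' subtype mix dominated by luminal and basal, 1000 features per continuous
#' data type, and GI50s centred at 7 (-log10 molar, i.e. 100 nM) with a
#' between-line spread of 1 log10 unit for driven compounds.
#'
#' @param n_lines Number of cell lines.
#' @param subtype_props Named proportions over luminal, basal, claudin_low,
#'   normal_like (must sum to 1).
#' @param data_types Continuous data types to generate.
#' @param n_features Features per continuous data type.
#' @param compounds Tibble with one row per compound: `compound`,
#'   `driver` (one of `"feature"`, `"subtype"`, `"mixed"`, `"null"`),
#'   `n_planted`, `effect_size` (SD units), `gi50_base` (-log10 M),
#'   `gi50_spread` (log10 units), `gi50_noise_sd`. Built with
#'   [design_compound()] helpers or by hand.
#' @param subtype_frac Fraction of features per data type carrying
#'   subtype-dependent mean shifts.
#' @param subtype_effect SD units of the subtype mean shifts.
#' @param seed Integer seed recorded in all outputs.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_lines = 48,
                              subtype_props = c(luminal = 0.44, basal = 0.34,
                                                claudin_low = 0.13,
                                                normal_like = 0.09),
                              data_types = c("expression_array",
                                             "copy_number", "methylation"),
                              n_features = 1000,
                              compounds = design_compound("drug_A"),
                              subtype_frac = 0.1,
                              subtype_effect = 1.5,
                              seed = 1) {
  if (abs(sum(subtype_props) - 1) > 1e-8) {
    abort("Subtype proportions must sum to 1.")
  }
  if (any(compounds$effect_size < 0)) abort("Effect sizes must be >= 0.")
  structure(list(n_lines = n_lines, subtype_props = subtype_props,
                 data_types = data_types, n_features = n_features,
                 compounds = as_tibble(compounds),
                 subtype_frac = subtype_frac,
                 subtype_effect = subtype_effect, seed = seed),
            class = "simulation_design")
}

#' One compound row for a simulation design
#'
#' @param compound Compound id.
#' @param driver `"feature"` (response driven by planted omic features),
#'   `"subtype"` (by transcriptional subtype), `"mixed"`, or `"null"`.
#' @param n_planted Planted features per data type (feature/mixed drivers).
#' @param effect_size Planted-feature shift in SD units.
#' @param gi50_base Panel-mean GI50, -log10 molar.
#' @param gi50_spread GI50 swing attributable to the driver (log10 units).
#' @param gi50_noise_sd Residual GI50 noise (log10 units).
#' @return One-row tibble.
#' @export
design_compound <- function(compound, driver = "feature", n_planted = 15,
                            effect_size = 2, gi50_base = 7, gi50_spread = 1,
                            gi50_noise_sd = 0.1) {
  tibble(compound = compound, driver = driver, n_planted = n_planted,
         effect_size = effect_size, gi50_base = gi50_base,
         gi50_spread = gi50_spread, gi50_noise_sd = gi50_noise_sd)
}

#' Simulate a multi-omic cell-line panel with known ground truth
#'
#' Subtypes are drawn from the design proportions; each continuous data type
#' is standard normal noise plus subtype-dependent mean shifts on a fraction
#' of features plus planted per-compound effects; the seven-gene mutation
#' panel is Bernoulli with subtype-dependent rates (TP53 enriched in
#' basal/claudin-low, PIK3CA and CDH1 in luminal). For a feature-driven
#' compound a latent per-line burden drives both the planted features
#' (`effect_size * burden + noise`) and the true GI50
#' (`gi50_base + gi50_spread * burden + noise`); subtype-driven compounds
#' shift GI50 for the target subtype instead.
#'
#' @param design A [simulation_design()].
#' @return List with `omics` (named list of [omic_dataset()]s, including
#'   `mutation`), `annotation` ([subtype_annotation()] tibble), `response`
#'   (tibble `cell_line`, `compound`, `gi50` of true values), `truth` (per
#'   compound: planted feature ids per data type, driver, target subtype,
#'   latent burden).
#' @export
simulate_panel <- function(design) {
  withr::with_seed(design$seed, {
    n <- design$n_lines
    lines <- sprintf("CL%03d", seq_len(n))
    subtype <- sample(names(design$subtype_props), n, replace = TRUE,
                      prob = design$subtype_props)
    erbb2 <- rbinom(n, 1, ifelse(subtype == "luminal", 0.4,
                                 ifelse(subtype == "basal", 0.25, 0.05))) == 1
    annotation <- subtype_annotation(tibble(
      sample_id = lines, subtype = subtype, erbb2_amplified = erbb2,
      er_status = subtype == "luminal"))

    omics <- list()
    planted_pool <- list()
    for (dt in design$data_types) {
      p <- design$n_features
      ids <- sprintf("G%s%04d|gene", toupper(substr(dt, 1, 2)), seq_len(p))
      M <- matrix(rnorm(n * p), n, p, dimnames = list(lines, ids))
      n_sub <- ceiling(design$subtype_frac * p)
      sub_idx <- sample(p, n_sub)
      shifts <- matrix(rnorm(length(design$subtype_props) * n_sub,
                             sd = design$subtype_effect),
                       length(design$subtype_props), n_sub,
                       dimnames = list(names(design$subtype_props), NULL))
      M[, sub_idx] <- M[, sub_idx] + shifts[subtype, , drop = FALSE]
      omics[[dt]] <- M
      # features free of subtype structure, reserved for planting
      planted_pool[[dt]] <- setdiff(seq_len(p), sub_idx)
    }

    truth <- list()
    response <- list()
    subtype_cycle <- rep(c("luminal", "basal"),
                         length.out = nrow(design$compounds))
    for (i in seq_len(nrow(design$compounds))) {
      cm <- design$compounds[i, ]
      burden <- rnorm(n)
      target <- subtype_cycle[i]
      planted <- list()
      driver_term <- switch(cm$driver,
        feature = burden,
        subtype = as.numeric(subtype == target),
        mixed = (burden + as.numeric(subtype == target)) / sqrt(2),
        null = rep(0, n),
        abort(sprintf("Unknown driver '%s'.", cm$driver)))
      if (cm$driver %in% c("feature", "mixed") && cm$n_planted > 0) {
        for (dt in design$data_types) {
          take <- sample(planted_pool[[dt]],
                         min(cm$n_planted, length(planted_pool[[dt]])))
          planted_pool[[dt]] <- setdiff(planted_pool[[dt]], take)
          omics[[dt]][, take] <- omics[[dt]][, take] + cm$effect_size * burden
          planted[[dt]] <- colnames(omics[[dt]])[take]
        }
      }
      gi50 <- cm$gi50_base + cm$gi50_spread * driver_term +
        rnorm(n, sd = cm$gi50_noise_sd)
      response[[i]] <- tibble(cell_line = lines, compound = cm$compound,
                              gi50 = gi50)
      truth[[cm$compound]] <- list(driver = cm$driver, planted = planted,
                                   target_subtype = target, burden = burden)
    }

    mut_rates <- list(
      TP53 = c(luminal = 0.35, basal = 0.8, claudin_low = 0.7,
               normal_like = 0.3),
      PIK3CA = c(luminal = 0.45, basal = 0.15, claudin_low = 0.2,
                 normal_like = 0.2),
      MLL3 = c(luminal = 0.15, basal = 0.15, claudin_low = 0.15,
               normal_like = 0.1),
      CDH1 = c(luminal = 0.2, basal = 0.05, claudin_low = 0.1,
               normal_like = 0.05),
      MAP2K4 = c(luminal = 0.12, basal = 0.08, claudin_low = 0.1,
                 normal_like = 0.05),
      PTEN = c(luminal = 0.08, basal = 0.2, claudin_low = 0.25,
               normal_like = 0.1),
      NCOR1 = c(luminal = 0.1, basal = 0.12, claudin_low = 0.1,
                normal_like = 0.05))
    Mmut <- sapply(names(mut_rates), function(g) {
      rbinom(n, 1, mut_rates[[g]][subtype])
    })
    rownames(Mmut) <- lines
    colnames(Mmut) <- paste0(names(mut_rates), "|gene")

    omic_list <- purrr::imap(omics, ~ omic_dataset(.x, .y))
    omic_list$mutation <- omic_dataset(Mmut, "mutation")
    list(omics = omic_list, annotation = annotation,
         response = bind_rows(response), truth = truth, seed = design$seed)
  })
}

#' Simulate raw dose-response plates consistent with true GI50s
#'
#' Inverts the dose-response model: for each (line, compound) a percent-
#' growth line in log10(concentration) crosses 50 exactly at the true GI50
#' (slope `slope` percent per decade), is converted to signals with time-zero
#' 100 and untreated control 200 (so signal = 100 + growth in both
#' branches), and written as OD triplicates with plate background and
#' optional multiplicative noise. True GI50s outside the tested range yield
#' off-scale curves that exercise clamping.
#'
#' @param response Tibble `cell_line`, `compound`, `gi50` of true values
#'   (-log10 molar), e.g. from [simulate_panel()].
#' @param c_min,c_max Lowest and highest tested molar concentrations (9
#'   log-spaced points).
#' @param slope Growth decrease per decade of concentration. The default 70
#'   describes a steep responder (Hill slope near 1.5), for which assay-level
#'   OD noise propagates only weakly into the interpolated GI50.
#' @param od_cv Multiplicative OD noise (coefficient of variation); 0 gives
#'   an exact round trip.
#' @param background Plate background OD.
#' @param seed Integer seed.
#' @return Tibble in the [read_plate_file()] schema.
#' @export
simulate_plates <- function(response, c_min = 1e-9, c_max = 1e-5,
                            slope = 70, od_cv = 0, background = 10,
                            seed = 1) {
  conc <- 10^seq(log10(c_min), log10(c_max), length.out = 9)
  t0 <- 100; control <- 200
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(response)), function(i) {
      gi <- response$gi50[i]
      g <- 50 - slope * (log10(conc) + gi)  # crosses 50 at conc = 10^-gi
      g <- pmax(g, -98)                     # growth bounded below by -100
      treated <- 100 + g
      noisy <- function(v, k) v * (1 + if (od_cv > 0)
        rnorm(k, sd = od_cv) else 0)
      od0 <- noisy(rep(control, 3), 3) + background
      odt <- lapply(treated, function(tv) noisy(rep(tv, 3), 3) + background)
      rec <- c(list(cellline = response$cell_line[i],
                    compound = response$compound[i],
                    drug_plate_id = sprintf("DP%05d", i),
                    T0_plate_id = sprintf("TP%05d", i),
                    background_od1 = background, background_od2 = background),
               setNames(as.list(od0), paste0("od0.", 1:3)),
               setNames(as.list(unlist(odt)),
                        as.vector(t(outer(1:9, 1:3,
                                          function(j, r) paste0("od", j, ".", r))))),
               list(T0_background_od1 = background,
                    T0_background_od2 = background,
                    T0_median_od = t0 + background),
               setNames(as.list(conc), paste0("c", 1:9)),
               list(units = "M"))
      as_tibble(rec)
    })
    bind_rows(rows)
  })
}

#' Simulate a tumor cohort carrying a planted response signature
#'
#' Patients are drawn with the same subtype structure and feature grammar as
#' the cell-line panel; a known fraction are responders whose planted
#' signature features are shifted by the effect size. Ground-truth status is
#' returned for toolbox testing.
#'
#' @param panel A [simulate_panel()] result.
#' @param compound Compound whose planted truth drives the cohort.
#' @param n_patients Number of tumors.
#' @param responder_fraction Fraction of responders.
#' @param effect_size SD shift of planted features in responders; default
#'   the panel design's value for this compound.
#' @param seed Integer seed.
#' @return List with `profiles` (named list of [omic_dataset()]s), `status`
#'   (tibble `patient`, `responder`).
#' @export
simulate_tumor_cohort <- function(panel, compound, n_patients = 300,
                                  responder_fraction = 0.3,
                                  effect_size = 2, seed = 1) {
  tr <- panel$truth[[compound]]
  if (is.null(tr)) abort(sprintf("Compound '%s' not in panel truth.", compound))
  withr::with_seed(seed, {
    patients <- sprintf("TB%04d", seq_len(n_patients))
    responder <- runif(n_patients) < responder_fraction
    profiles <- purrr::imap(panel$omics, function(ds, dt) {
      if (dt == "mutation") return(NULL)
      p <- ncol(ds$values)
      M <- matrix(rnorm(n_patients * p), n_patients, p,
                  dimnames = list(patients, colnames(ds$values)))
      pl <- tr$planted[[dt]]
      if (!is.null(pl) && length(pl) > 0) {
        M[responder, pl] <- M[responder, pl] + effect_size
      }
      omic_dataset(M, dt)
    })
    profiles <- profiles[!purrr::map_lgl(profiles, is.null)]
    list(profiles = profiles,
         status = tibble(patient = patients, responder = responder),
         seed = seed)
  })
}
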