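# Seeded synthetic fixtures: labeled property-profile tables with
# controllable class separation, per-endpoint descriptor training sets, and
# a small curated panel of real drug / reagent-like SMILES for end-to-end
# smoke tests.  Distribution choices (lognormal MW, logit-normal ADMET
# coordinates) are fixture conventions that emulate the drug-vs-non-drug
# profile structure, not claims about any particular dataset.

#' Configuration for the synthetic profile generator
#'
#' @param n_per_class samples per class.
#' @param pc_effect length-6 standardized mean shifts applied to the
#'   non-drug class on the physicochemical block (mw, logp, tpsa, hba, hbd,
#'   nrot), in units of each coordinate's spread.
#' @param admet_effect length-20 mean shifts on the logit scale subtracted
#'   from the non-drug class's ADMET coordinates.
#' @param noise_sd standard deviation of the latent logit noise.
#' @param seed integer seed; fully determines the output.
#' @return list of class `profile_generator_config`.
#' @export
profile_generator_config <- function(n_per_class = 1000L,
                                     pc_effect = rep(0, 6),
                                     admet_effect = rep(0, 20),
                                     noise_sd = 1,
                                     seed = 1L) {
  if (length(pc_effect) == 1L) pc_effect <- rep(pc_effect, 6)
  if (length(admet_effect) == 1L) admet_effect <- rep(admet_effect, 20)
  stopifnot(length(pc_effect) == 6L, length(admet_effect) == 20L,
            noise_sd > 0, n_per_class >= 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 pc_effect = as.numeric(pc_effect),
                 admet_effect = as.numeric(admet_effect),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "profile_generator_config")
}

# drug-like base distributions for the 6 physicochemical coordinates and
# their nominal spreads (used to convert standardized shifts to raw units)
.pc_spreads <- c(mw = 120, logp = 1.8, tpsa = 35, hba = 2, hbd = 1.5,
                 nrot = 3)

#' Generate a labeled synthetic property-profile table
#'
#' Drug-class physicochemical values are drawn from plausible drug-like
#' distributions (lognormal MW around 350 g/mol, gamma-like TPSA, Poisson
#' counts); the non-drug class is shifted by `pc_effect` spread units.
#' ADMET coordinates are inverse-logit transforms of class-dependent
#' normals whose means differ by `admet_effect` on the logit scale, so the
#' per-coordinate generative AUC is `pnorm(effect / (sqrt(2) * noise_sd))`.
#'
#' @param config a [profile_generator_config()].
#' @return list with `pc` (n x 6 matrix), `admet` (n x 20 matrix in
#'   `[0, 1]`), `label` (1 = drug, 0 = non-drug) and the `config`.
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "profile_generator_config"))
  n <- config$n_per_class
  .with_seed(config$seed, {
    draw_pc <- function(m, shift) {
      cbind(
        mw = stats::rlnorm(m, log(350), 0.35) + shift[1] * .pc_spreads[1],
        logp = stats::rnorm(m, 2.5, 1.8) + shift[2] * .pc_spreads[2],
        tpsa = stats::rgamma(m, shape = 4, scale = 20) + shift[3] * .pc_spreads[3],
        hba = stats::rpois(m, 4) + shift[4] * .pc_spreads[4],
        hbd = stats::rpois(m, 2) + shift[5] * .pc_spreads[5],
        nrot = stats::rpois(m, 5) + shift[6] * .pc_spreads[6]
      )
    }
    admet_mu_drug <- rep(1, 20)
    draw_admet <- function(m, mu) {
      z <- matrix(stats::rnorm(m * 20, rep(mu, each = m), config$noise_sd),
                  m, 20)
      stats::plogis(z)
    }
    pc <- rbind(draw_pc(n, rep(0, 6)), draw_pc(n, config$pc_effect))
    admet <- rbind(draw_admet(n, admet_mu_drug),
                   draw_admet(n, admet_mu_drug - config$admet_effect))
    colnames(admet) <- default_panel()$name
    list(pc = pc, admet = admet,
         label = c(rep(1, n), rep(0, n)), config = config)
  })
}

#' Generate a synthetic endpoint training table
#'
#' Two-class Gaussian table over the 200 pinned descriptor names; the
#' class-mean shift `effect` is placed on a seeded random subset of 20
#' features, the rest are pure noise.  Balanced labels.
#'
#' @param n total number of rows (split evenly between classes).
#' @param effect standardized mean shift carried by the informative
#'   features.
#' @param seed integer seed.
#' @param n_informative number of informative features (default 20).
#' @return data.frame with `label` (0/1) and 200 descriptor columns.
#' @export
generate_endpoint_dataset <- function(n, effect = 0, seed = 1L,
                                      n_informative = 20L) {
  stopifnot(n >= 2L)
  n1 <- n %/% 2L; n0 <- n - n1
  nm <- descriptor_names()
  .with_seed(seed, {
    info <- sample.int(200L, n_informative)
    x <- matrix(stats::rnorm(n * 200L), n, 200L, dimnames = list(NULL, nm))
    x[seq_len(n1), info] <- x[seq_len(n1), info] + effect / 2
    x[seq.int(n1 + 1L, n), info] <- x[seq.int(n1 + 1L, n), info] - effect / 2
    cbind(data.frame(label = c(rep(1L, n1), rep(0L, n0))),
          as.data.frame(x))
  })
}

#' Curated fixture molecules
#'
#' Forty named structures -- twenty approved drugs and twenty reagent-like
#' small molecules -- that all pass standardization; used for featurizer
#' oracle tests and end-to-end smoke runs.
#'
#' @return data.frame with `name`, `smiles`, `class` (`drug`/`nondrug`).
#' @export
fixture_molecules <- function() {
  drugs <- c(
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    naproxen = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    diazepam = "CN1c2ccc(Cl)cc2C(=Nc3ccccc3)CC1=O",
    lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    metoprolol = "COCCc1ccc(OCC(O)CNC(C)C)cc1",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    phenytoin = "O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1",
    carbamazepine = "NC(=O)N1c2ccccc2C=Cc2ccccc21",
    chlorpromazine = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    haloperidol = "OC1(c2ccc(Cl)cc2)CCN(CCCC(=O)c2ccc(F)cc2)CC1",
    diphenhydramine = "CN(C)CCOC(c1ccccc1)c1ccccc1",
    cimetidine = "CC1=C(CSCCNC(=NC)NC#N)N=CN1",
    sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
    amoxicillin = "CC1(C)SC2C(NC(=O)C(N)c3ccc(O)cc3)C(=O)N2C1C(=O)O"
  )
  nondrugs <- c(
    ethanol = "CCO",
    acetone = "CC(C)=O",
    toluene = "Cc1ccccc1",
    hexane = "CCCCCC",
    dmso = "CS(C)=O",
    thf = "C1CCOC1",
    ethyl_acetate = "CCOC(C)=O",
    acetonitrile = "CC#N",
    pyridine = "c1ccncc1",
    aniline = "Nc1ccccc1",
    phenol = "Oc1ccccc1",
    benzaldehyde = "O=Cc1ccccc1",
    benzoic_acid = "O=C(O)c1ccccc1",
    cyclohexane = "C1CCCCC1",
    octanol = "CCCCCCCCO",
    glycerol = "OCC(O)CO",
    urea = "NC(N)=O",
    triethylamine = "CCN(CC)CC",
    diethyl_ether = "CCOCC",
    triacontane = "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"
  )
  data.frame(
    name = c(names(drugs), names(nondrugs)),
    smiles = unname(c(drugs, nondrugs)),
    class = rep(c("drug", "nondrug"), each = 20L),
    stringsAsFactors = FALSE
  )
}
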