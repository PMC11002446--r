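#' Preset structural causal models emulating the three food-quality studies
#'
#' Returns a ground-truth [make_scm()] spec for one of three synthetic study
#' designs. The presets mimic the *structure* of the corresponding real
#' datasets (variable counts, kinds, graph topology, qualitative correlation
#' ranges and effect signs), not their measured values; all coefficients are
#' fixed, documented constants.
#'
#' \describe{
#' \item{wheat}{45 continuous predictors of a continuous baking-quality
#'   outcome (`volume`). Exactly 10 variables (protein, wet gluten, falling
#'   number, water absorption, dough resistance, resistance/extensibility
#'   ratio, total glutenin, total high-molecular-mass glutenin subunits,
#'   alpha-gliadin, degree of softening) carry directed paths into `volume`;
#'   each is also a direct parent, so all ten have nonzero partial effects
#'   and are recoverable by sparse regression. The remaining 35 variables
#'   (HPLC fractions, extra farinograph/extensograph channels) are correlated
#'   distractors loading on four shared hub variables, giving the strongly
#'   collinear table typical of cereal-quality assays.}
#' \item{dairy}{A consumer study: continuous pre-treatment `temperature`
#'   (deg C) and `fat` content are exogenous; `pH` and `colour` are continuous
#'   children of temperature; `odour` and `turbidity` are binary (thresholded
#'   latent) children of temperature; binary `taste` is a collider with
#'   parents temperature, colour and fat; the 3-level ordinal `grade`
#'   (low/medium/high) is a collider with parents temperature, turbidity,
#'   odour and fat. The temperature effect on grade combines a linear decline
#'   with a saturating (softplus) drop centred at 60 deg C, so the
#'   intervention curve bends downward through that change point.}
#' \item{wine}{11 continuous physicochemical variables plus a 10-level
#'   ordinal `quality`. Quality's parents are alcohol (+0.35),
#'   volatile_acidity (-0.20), sulphates (+0.15) and free_sulfur_dioxide
#'   (+0.10) in standardized latent units; the remaining variables are
#'   connected only as non-ancestors of quality (e.g. density is a collider
#'   of alcohol and residual sugar), so every predictor's total effect on
#'   quality equals its partial effect given the others.}
#' }
#'
#' @param name one of `"wheat"`, `"dairy"`, `"wine"`.
#' @param seed accepted for interface stability and ignored: the presets are
#'   fixed constants; randomness enters only through [sample_dataset()].
#' @return an `scm_spec`.
#' @examples
#' scm <- food_template("dairy")
#' dag_parents(scm$dag, "grade")
#' @export
food_template <- function(name = c("wheat", "dairy", "wine"), seed = NULL) {
  name <- match.arg(name)
  switch(name,
         dairy = template_dairy(),
         wine = template_wine(),
         wheat = template_wheat())
}

template_dairy <- function() {
  nodes <- c("temperature", "fat", "pH", "colour", "odour", "turbidity",
             "taste", "grade")
  edges <- rbind(
    c("temperature", "pH"), c("temperature", "colour"),
    c("temperature", "odour"), c("temperature", "turbidity"),
    c("temperature", "taste"), c("temperature", "grade"),
    c("fat", "taste"), c("fat", "grade"),
    c("turbidity", "grade"), c("odour", "grade"),
    c("colour", "taste"))
  g <- dag(nodes, edges)
  coefs <- c(
    "temperature->pH"     = -0.040,
    "temperature->colour" = -0.050,
    "temperature->odour"  =  0.050,   # heat treatment raises off-odour risk
    "temperature->turbidity" = 0.070,
    "temperature->taste"  = -0.040,
    "temperature->grade"  = -0.030,   # linear part; saturating drop added below
    "fat->taste"          =  0.600,
    "fat->grade"          =  0.450,
    "turbidity->grade"    = -0.700,
    "odour->grade"        = -0.700,
    "colour->taste"       =  0.500)
  noise <- c(temperature = 13, fat = 1, pH = 0.5, colour = 0.6, odour = 1,
             turbidity = 1, taste = 1.5, grade = 0.8)
  # intercepts centre every latent at ~0 (binary thresholds at 0);
  # temperature mean 48 deg C, fat mean 3 %
  intercepts <- c(
    temperature = 48, fat = 3,
    pH = 6.6 + 0.040 * 48,
    colour = 100 + 0.050 * 48,
    odour = -0.050 * 48,
    turbidity = -0.070 * 48,
    taste = 0.040 * 48 - 0.600 * 3 - 0.500 * 100,
    # E[softplus term] ~ 2.25 at these temperature settings
    grade = 0.030 * 48 + 0.100 * 2.25 - 0.450 * 3 + 0.700 * 0.5 + 0.700 * 0.5)
  kinds <- list(
    odour = list(kind = "binary", threshold = 0),
    turbidity = list(kind = "binary", threshold = 0),
    taste = list(kind = "binary", threshold = 0),
    grade = list(kind = "ordinal", cut_points = c(-0.6, 0.7),
                 labels = c("low", "medium", "high")))
  # temperature -> grade: linear decline of -0.030 per deg C plus a softplus
  # drop ~3.33x as steep beyond the 60 deg C change point, i.e. the latent
  # slope saturates at -0.030 - 0.100 * sigmoid((T - 60)/5)
  transforms <- list(
    "temperature->grade" = list(type = "linear_saturating", center = 60,
                                scale = 5, ratio = 10 / 3))
  make_scm(g, coefficients = coefs, noise_sd = noise, kinds = kinds,
           intercepts = intercepts, transforms = transforms)
}

template_wine <- function() {
  nodes <- c("fixed_acidity", "volatile_acidity", "citric_acid",
             "residual_sugar", "chlorides", "free_sulfur_dioxide",
             "total_sulfur_dioxide", "density", "pH", "sulphates", "alcohol",
             "quality")
  edges <- rbind(
    c("fixed_acidity", "pH"), c("fixed_acidity", "citric_acid"),
    c("volatile_acidity", "citric_acid"),
    c("free_sulfur_dioxide", "total_sulfur_dioxide"),
    c("alcohol", "density"), c("residual_sugar", "density"),
    c("alcohol", "quality"), c("volatile_acidity", "quality"),
    c("sulphates", "quality"), c("free_sulfur_dioxide", "quality"))
  g <- dag(nodes, edges)
  coefs <- c(
    "fixed_acidity->pH" = -0.70,
    "fixed_acidity->citric_acid" = 0.60,
    "volatile_acidity->citric_acid" = -0.35,
    "free_sulfur_dioxide->total_sulfur_dioxide" = 0.80,
    "alcohol->density" = -0.55,
    "residual_sugar->density" = 0.60,
    "alcohol->quality" = 0.35,
    "volatile_acidity->quality" = -0.20,
    "sulphates->quality" = 0.15,
    "free_sulfur_dioxide->quality" = 0.10)
  noise <- c(fixed_acidity = 1, volatile_acidity = 1, citric_acid = 0.7,
             residual_sugar = 1, chlorides = 1, free_sulfur_dioxide = 1,
             total_sulfur_dioxide = 0.6, density = 0.5, pH = 0.7,
             sulphates = 1, alcohol = 1, quality = 0.85)
  kinds <- list(
    quality = list(kind = "ordinal",
                   cut_points = c(-2.8, -2.0, -1.2, -0.45, 0.25, 1.0, 1.8,
                                  2.6, 3.4),
                   labels = as.character(1:10)))
  make_scm(g, coefficients = coefs, noise_sd = noise, kinds = kinds)
}

template_wheat <- function() {
  active <- c("protein", "wet_gluten", "falling_number", "water_absorption",
              "dough_resistance", "resist_ext_ratio", "total_glutenin",
              "thmm", "alpha_gliadin", "softening_degree")
  distract <- c(sprintf("hplc_f%02d", 1:25), paste0("farino_", 1:5),
                paste0("exten_", 1:3), paste0("misc_", 1:2))
  nodes <- c(active, distract, "volume")
  hubs <- c("protein", "water_absorption", "falling_number", "alpha_gliadin")
  edges <- rbind(
    c("protein", "wet_gluten"), c("protein", "total_glutenin"),
    c("protein", "thmm"), c("thmm", "dough_resistance"),
    c("dough_resistance", "resist_ext_ratio"),
    c("water_absorption", "softening_degree"))
  coefs <- c(
    "protein->wet_gluten" = 0.80, "protein->total_glutenin" = 0.70,
    "protein->thmm" = 0.60, "thmm->dough_resistance" = 0.50,
    "dough_resistance->resist_ext_ratio" = 0.60,
    "water_absorption->softening_degree" = -0.50)
  # distractors load on two of the four hub variables; loadings are fixed
  # constants derived from the distractor index
  for (j in seq_along(distract)) {
    h1 <- hubs[(j - 1) %% 4 + 1]
    h2 <- hubs[j %% 4 + 1]
    edges <- rbind(edges, c(h1, distract[j]), c(h2, distract[j]))
    l1 <- 0.65 + 0.02 * (j %% 5)
    l2 <- 0.50 * (-1)^j
    coefs[paste0(h1, "->", distract[j])] <- l1
    coefs[paste0(h2, "->", distract[j])] <- l2
  }
  vol_coefs <- c(protein = 0.45, wet_gluten = 0.15, falling_number = 0.20,
                 water_absorption = 0.18, dough_resistance = 0.15,
                 resist_ext_ratio = 0.15, total_glutenin = 0.20, thmm = 0.25,
                 alpha_gliadin = 0.15, softening_degree = -0.20)
  for (v in names(vol_coefs)) {
    edges <- rbind(edges, c(v, "volume"))
    coefs[paste0(v, "->volume")] <- vol_coefs[[v]]
  }
  noise <- stats::setNames(rep(1, length(nodes)), nodes)
  noise[c("wet_gluten", "total_glutenin")] <- c(0.6, 0.7)
  noise[c("thmm", "dough_resistance", "resist_ext_ratio",
          "softening_degree")] <- c(0.8, 0.85, 0.8, 0.85)
  noise[distract] <- 0.45
  noise["volume"] <- 0.35
  make_scm(dag(nodes, edges), coefficients = coefs, noise_sd = noise)
}

#' Names of the planted active predictors of a template outcome
#'
#' For the wheat template these are the ten variables with directed paths
#' into `volume`; for wine, the parents of `quality`; for dairy, the parents
#' of `grade`. Used as the recovery ground truth in tests and reports.
#' @param name template name.
#' @export
template_active_set <- function(name = c("wheat", "dairy", "wine")) {
  name <- match.arg(name)
  scm <- food_template(name)
  outcome <- switch(name, wheat = "volume", dairy = "grade", wine = "quality")
  nodes <- setdiff(dag_nodes(scm$dag), outcome)
  nodes[vapply(nodes, function(v)
    has_directed_path(scm$dag$amat, match(v, dag_nodes(scm$dag)),
                      match(outcome, dag_nodes(scm$dag))), TRUE)]
}
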