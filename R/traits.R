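#' Craniometric trait registry
#'
#' The package works with a fixed registry of 25 standard cranio-dental
#' measurements (mm; occlusal surface area, OSA, is recorded in mm^2 and
#' carried through the log-scale analyses as its square root).  Each trait
#' has a short code, a description, and three roles:
#'
#' * `bilateral` -- measured on both sides of the skull; field sheets may
#'   carry `<CODE>_L` / `<CODE>_R` columns that are averaged on ingest.
#' * `in_gms` -- member of the geometric-mean-size subset: the 22 major
#'   dimensions, i.e. everything except the two minor zygoma measures
#'   (`ZH`, `ZW`) and the areal trait `OSA`.
#' * `in_shape` -- enters the default shape-variable set (all 25 traits,
#'   OSA as its square root).
#'
#' @return A data frame with one row per trait and columns `code`,
#'   `description`, `units`, `bilateral`, `areal`, `in_gms`, `in_shape`.
#' @examples
#' reg <- trait_registry()
#' sum(reg$in_gms)   # 22 major dimensions
#' @export
trait_registry <- function() {
  tr <- function(code, description, bilateral = FALSE, areal = FALSE) {
    data.frame(code = code, description = description,
               units = if (areal) "mm^2" else "mm",
               bilateral = bilateral, areal = areal,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    tr("TL",  "total skull length, rostrum tip to nuchal crest"),
    tr("BCL", "braincase length, nuchal crest apex to postorbital constriction"),
    tr("BCW", "braincase width posterior to zygomatic arches"),
    tr("CBL", "condylobasal length"),
    tr("FL",  "face length, fronto-nasal suture to premaxilla tip"),
    tr("IOD", "interorbital distance"),
    tr("PL",  "palatal length"),
    tr("PW",  "palatal width posterior to last upper molars"),
    tr("RWC", "rostral width at canines"),
    tr("RWM", "rostral width at last upper molars"),
    tr("MW",  "mastoid-to-mastoid width"),
    tr("OSA", "occlusal surface area of the postcanine tooth row", areal = TRUE),
    tr("GSW", "greatest squamosal (skull) width"),
    tr("ZW",  "zygoma width (arch thickness)", bilateral = TRUE),
    tr("ZL",  "zygoma length", bilateral = TRUE),
    tr("ZH",  "zygoma height", bilateral = TRUE),
    tr("ZFW", "zygomatic fossa width", bilateral = TRUE),
    tr("ZFL", "zygomatic fossa length", bilateral = TRUE),
    tr("JW",  "jaw width, condyle to condyle"),
    tr("JL",  "jaw length, symphysis tip to condyle", bilateral = TRUE),
    tr("MRH", "mandibular ramus height", bilateral = TRUE),
    tr("MRW", "mandibular ramus width", bilateral = TRUE),
    tr("MAM", "moment arm of the masseter", bilateral = TRUE),
    tr("MAT", "moment arm of the temporalis", bilateral = TRUE),
    tr("OLC", "out-lever at the carnassial", bilateral = TRUE)
  )
  # GMS subset: the major dimensions, excluding the minor zygoma measures
  # (roughly 10-fold smaller than the rest) and the areal OSA.
  reg$in_gms <- !(reg$code %in% c("ZH", "ZW", "OSA"))
  reg$in_shape <- TRUE
  stopifnot(!anyDuplicated(reg$code), sum(reg$areal) == 1L)
  reg
}

#' Trait code subsets
#'
#' Convenience accessors for the trait subsets used throughout the
#' analyses: the 22-trait geometric-mean-size subset and the default
#' shape-variable set.
#'
#' @param registry a trait registry, as returned by [trait_registry()].
#' @return Character vector of trait codes.
#' @export
gms_traits <- function(registry = trait_registry()) {
  registry$code[registry$in_gms]
}

#' @rdname gms_traits
#' @export
shape_traits <- function(registry = trait_registry()) {
  registry$code[registry$in_shape]
}

#' Species and feeding-mode lookup
#'
#' The four study species and their fixed feeding orientation: river
#' otters and giant river otters capture prey with the mouth
#' (raptorial piscivores); Asian small-clawed otters and sea otters
#' capture prey by hand (invertebrate specialists).  The mapping is a
#' fixed lookup rather than user data so labels cannot drift.
#'
#' @return A data frame with columns `species` and `feeding_mode`.
#' @export
species_registry <- function() {
  data.frame(
    species = c("river", "giant_river", "small_clawed", "sea"),
    feeding_mode = c("mouth", "mouth", "hand", "hand"),
    stringsAsFactors = FALSE
  )
}

#' Sea otter subspecies labels
#' @return Character vector: northern, russian, southern.
#' @export
sea_otter_subspecies <- function() c("northern", "russian", "southern")

#' Feeding mode for a species label
#' @param species character vector of species labels.
#' @return Character vector of feeding modes ("mouth" or "hand").
#' @export
feeding_mode_of <- function(species) {
  reg <- species_registry()
  idx <- match(species, reg$species)
  if (anyNA(idx)) {
    stop("unknown species label(s): ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  reg$feeding_mode[idx]
}
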