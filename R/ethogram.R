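#' Ethogram of scan-sampled activity patterns
#'
#' Mapping from fine activity patterns to the six behavioural categories
#' used in time budgets and synchrony (foraging, rest, locomotion,
#' social, vigilance, other). Scan records are validated against it.
#'
#' @return data.frame with columns `activity_pattern`, `behaviour_category`.
#' @export
#' @examples
#' ethogram_activities()
ethogram_activities <- function() {
  data.frame(
    activity_pattern = c(
      "drink", "feed_on_hay", "graze",
      "lay", "head_to_tail", "stand",
      "gallop", "trot", "walk",
      "scratch", "wallow",
      "mutual_grooming",
      "observe"
    ),
    behaviour_category = c(
      "foraging", "foraging", "foraging",
      "rest", "rest", "rest",
      "locomotion", "locomotion", "locomotion",
      "other", "other",
      "social",
      "vigilance"
    ),
    stringsAsFactors = FALSE
  )
}

#' Ethogram of social interactions
#'
#' All-occurrence interaction subtypes with their kind (affiliative or
#' agonistic) and, for agonistic subtypes, the role class of the actor
#' (offensive aggressor vs defensive/submissive animal). The role class
#' drives the win-direction rule of [win_matrix()].
#'
#' @return data.frame with columns `subtype`, `kind`, `role_class`.
#' @export
ethogram_interactions <- function() {
  data.frame(
    subtype = c(
      "mutual_grooming", "mutual_sniffing", "rubbing",
      "bite", "bite_threat", "ear_threat", "harassment", "kick_threat",
      "kick", "avoidance"
    ),
    kind = c(rep("affiliative", 3), rep("agonistic", 7)),
    role_class = c(
      rep(NA_character_, 3),
      rep("offensive", 5),
      rep("defensive", 2)
    ),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
behaviour_categories <- function() {
  c("foraging", "rest", "locomotion", "social", "vigilance", "other")
}
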