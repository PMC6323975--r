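# Biochemical-uncertainty penalty scores.
#
# A rule supported by n distinct enzyme sequences gets penalty log10(n):
# 0 for a single sequence, 1 for ten, growing slowly -- a rule generated by
# many different enzymes is biochemically less specific.  n is counted per
# *distinct canonical rule* at each (diameter, stereo flag): the union of
# the accession sets of every parent reaction that yielded that rule.
# Rules with no annotation inherit the worst (largest) penalty observed at
# their diameter, the same conservative fallback used for on-the-fly rules.

#' Score a rule set by enzyme-sequence support
#'
#' @param ruleset an \code{rf_ruleset}.
#' @param annotations named list \code{reaction_id -> character vector} of
#'   sequence accessions (e.g. \code{\link{corpus_annotations}}), or a
#'   data.frame with columns \code{reaction_id}, \code{sequence_id}.
#' @return the rule set with columns \code{n_sequences}, \code{score}
#'   (the penalty) and \code{score_provenance} (\code{computed} or
#'   \code{worst-case}) added to its table.
#' @export
score_rules <- function(ruleset, annotations = list()) {
  if (is.data.frame(annotations)) {
    annotations <- split(annotations$sequence_id, annotations$reaction_id)
  }
  tab <- ruleset$table
  if (!nrow(tab)) {
    tab$n_sequences <- integer(0)
    tab$score <- numeric(0)
    tab$score_provenance <- character(0)
    ruleset$table <- tab
    return(ruleset)
  }
  key <- paste(tab$rule_smarts, tab$diameter, tab$is_stereo, sep = "\r")
  n_of_key <- vapply(split(tab$reaction_id, key), function(ids) {
    length(unique(unlist(annotations[unique(ids)])))
  }, 0L)
  n <- as.integer(n_of_key[key])
  penalty <- ifelse(n >= 1L, log10(n), NA_real_)
  provenance <- ifelse(n >= 1L, "computed", "worst-case")
  for (d in unique(tab$diameter)) {
    sel <- tab$diameter == d & is.na(penalty)
    if (any(sel)) {
      ref <- penalty[tab$diameter == d & !is.na(penalty)]
      penalty[sel] <- if (length(ref)) max(ref) else 0
    }
  }
  tab$n_sequences <- n
  tab$score <- penalty
  tab$score_provenance <- provenance
  ruleset$table <- tab
  ruleset
}

#' Score an on-the-fly (custom) rule against a reference database
#'
#' A custom rule identical to a stored rule (same canonical SMARTS, same
#' diameter, same stereo flag) inherits the stored penalty; a novel rule is
#' assigned the worst (largest) penalty present in the database at the
#' considered diameter -- our knowledge about it is at least as bad as the
#' worst case in the reference set.
#'
#' @param rule an \code{rf_rule} (canonicalized).
#' @param db path to a rule database created by \code{\link{export_db}}, or
#'   an open DBI connection.
#' @return list with \code{penalty}, \code{n_sequences} (NA for worst-case)
#'   and \code{provenance} (\code{inherited} or \code{worst-case}).
#' @export
score_custom_rule <- function(rule, db) {
  con <- db_connect(db)
  on.exit(db_disconnect(con, db), add = TRUE)
  d <- diameter_to_db(rule$diameter)
  hit <- DBI::dbGetQuery(con, paste(
    "SELECT r.score, r.n_sequences FROM rules r",
    "JOIN smarts s ON s.smarts_id = r.smarts_id",
    "WHERE s.smarts_string = ? AND r.diameter = ? AND r.isStereo = ?",
    "ORDER BY r.score LIMIT 1"),
    params = list(rule$rule_smarts, d, as.integer(rule$is_stereo)))
  if (nrow(hit)) {
    return(list(penalty = hit$score[1], n_sequences = hit$n_sequences[1],
                provenance = "inherited"))
  }
  worst <- DBI::dbGetQuery(con,
    "SELECT MAX(score) AS w, COUNT(*) AS n FROM rules WHERE diameter = ?",
    params = list(d))
  if (!nrow(worst) || worst$n[1] == 0L || is.na(worst$w[1]))
    stop(sprintf("no reference scores at diameter %s", format(rule$diameter)),
         call. = FALSE)
  list(penalty = worst$w[1], n_sequences = NA_integer_,
       provenance = "worst-case")
}
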