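# Published aggregate fixtures: the univariate contingency counts and the
# oral-frailty conditional probability table from the source study of 680
# maintenance-hemodialysis patients (388 without / 292 with oral frailty).
# Counts are stored as r x 2 matrices with columns (non-OF, OF).

of_table1_counts <- function() {
  m <- function(x, labels) matrix(x, ncol = 2, byrow = TRUE,
                                  dimnames = list(labels, c("non_OF", "OF")))
  list(
    age              = m(c(229, 93, 159, 199), c("<60", ">=60")),
    sex              = m(c(223, 178, 165, 114), c("Male", "Female")),
    polypharmacy     = m(c(224, 61, 164, 231), c("No", "Yes")),
    bmi              = m(c(58, 43, 194, 146, 99, 73, 37, 30),
                         c("Underweight", "Normal weight", "Overweight", "Obese")),
    poor_oral_health = m(c(120, 46, 268, 246), c("No", "Yes")),
    malnutrition     = m(c(235, 61, 153, 231), c("No", "Yes")),
    smoking          = m(c(300, 230, 88, 62), c("No", "Yes")),
    drinking         = m(c(299, 222, 89, 70), c("No", "Yes")),
    eating_alone     = m(c(222, 109, 166, 183), c("No", "Yes")),
    dietary_pattern  = m(c(226, 136, 81, 100, 81, 56),
                         c("Balanced", "Meat-dominant", "Vegetable-dominant")),
    general_frailty  = m(c(109, 22, 279, 270), c("No", "Yes")),
    depression       = m(c(314, 187, 74, 105), c("No", "Yes")),
    anxiety          = m(c(273, 191, 115, 101), c("No", "Yes")),
    marital_status   = m(c(22, 14, 327, 234, 39, 44),
                         c("Single/Unmarried", "Married", "Divorced/Widowed")),
    living_status    = m(c(338, 253, 50, 39), c("Not alone", "Alone")),
    social_support   = m(c(3, 38, 93, 159, 292, 95), c("Low", "Moderate", "High")),
    education        = m(c(73, 123, 215, 160, 100, 9),
                         c("Primary school or below", "Secondary school",
                           "College or above")),
    monthly_income   = m(c(59, 145, 96, 104, 129, 30, 104, 13),
                         c("<1000", "1000-3000", "3001-5000", ">5000")),
    medical_reimbursement = m(c(189, 135, 75, 48, 111, 102, 13, 7),
                              c("Urban employee", "Urban resident", "NCMS",
                                "Out-of-pocket"))
  )
}

# P(oral_frailty = yes) for the 16 parent configurations, ordered as in the
# published table: polypharmacy slowest, then malnutrition, eating alone,
# general frailty fastest.  Stored to 4 decimals, exactly as printed.
of_table3_pyes <- function() {
  g <- expand.grid(general_frailty = c("No", "Yes"), eating_alone = c("No", "Yes"),
                   malnutrition = c("No", "Yes"), polypharmacy = c("No", "Yes"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(polypharmacy = g$polypharmacy, malnutrition = g$malnutrition,
             eating_alone = g$eating_alone, general_frailty = g$general_frailty,
             p_yes = c(0.0833, 0.1750, 0.0789, 0.1066,
                       0.2083, 0.3302, 0.0882, 0.4434,
                       0.0789, 0.2750, 0.1389, 0.5000,
                       0.2045, 0.6158, 0.7500, 0.9246),
             stringsAsFactors = FALSE)
}

#' Packaged aggregate fixtures from the source study
#'
#' Returns the published univariate contingency counts (`table1`, one
#' `r x 2` count matrix per variable, columns = without / with oral
#' frailty) and the published oral-frailty conditional probability table
#' (`table3`, a 16-row data frame over the four direct parents), plus the
#' group sizes.  These are the machine-readable inputs behind the
#' reference network and the acceptance tests.
#'
#' @return a list with elements `table1`, `table3`, `n_total`,
#'   `n_of`, `n_non_of`.
#' @examples
#' fx <- load_fixtures()
#' fx$table1$polypharmacy
#' @export
load_fixtures <- function() {
  list(table1 = of_table1_counts(),
       table3 = of_table3_pyes(),
       n_total = 680L, n_of = 292L, n_non_of = 388L)
}
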