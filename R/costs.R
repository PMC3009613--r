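#' Visit schedule for one treatment strategy
#'
#' Direct medical costs per 3-month chronic-LBP cycle are built from a visit
#' schedule: each visit type has a per-visit reimbursement total (2009 KRW)
#' and a frequency per cycle. Only the per-visit-type totals are treated as
#' inputs; itemised fee lines underneath them live in the shipped config as
#' documentation.
#'
#' @param labels Character vector of visit-type labels.
#' @param unit_costs Per-visit cost in KRW, one per visit type.
#' @param frequencies Visits per 3-month cycle (non-negative integers).
#' @return A data frame of class `visit_schedule`.
#' @export
visit_schedule <- function(labels, unit_costs, frequencies) {
  if (length(labels) == 0) stop("empty visit schedule", call. = FALSE)
  if (length(unit_costs) != length(labels) ||
      length(frequencies) != length(labels)) {
    stop("labels, unit_costs and frequencies must have equal length", call. = FALSE)
  }
  if (any(unit_costs < 0) || any(frequencies < 0)) {
    stop("costs and frequencies must be >= 0", call. = FALSE)
  }
  if (any(frequencies != round(frequencies))) {
    stop("frequencies must be whole numbers of visits", call. = FALSE)
  }
  structure(
    data.frame(label = as.character(labels),
               unit_cost = as.numeric(unit_costs),
               frequency = as.integer(frequencies),
               stringsAsFactors = FALSE),
    class = c("visit_schedule", "data.frame")
  )
}

#' Direct medical cost of a visit schedule per cycle
#'
#' @param schedule A [visit_schedule()].
#' @return Total KRW per 3-month cycle, `sum(unit_cost * frequency)`.
#' @examples
#' usual <- visit_schedule(
#'   c("first visit", "regular visit", "simple visit"),
#'   c(53983, 31685, 10549), c(1, 6, 3))
#' visit_schedule_cost(usual)  # 275740
#' @export
visit_schedule_cost <- function(schedule) {
  stopifnot(inherits(schedule, "visit_schedule"))
  sum(schedule$unit_cost * schedule$frequency)
}

#' Indirect non-medical (productivity-loss) cost
#'
#' Productivity loss per patient: daily wage times the proportion of
#' economically active people times the employment rate, accumulated over
#' lost days. The base case applies a calibrated constant of 239,142 KRW per
#' 3-month chronic cycle (see [KRW_INDIRECT_PER_CYCLE]); this function is
#' the documented formula behind it.
#'
#' @param daily_wage Average daily wage, KRW.
#' @param prop_active Proportion of economically active people, in `[0, 1]`.
#' @param employment_rate Employment rate, in `[0, 1]`.
#' @param lost_days Work days lost per cycle.
#' @return KRW per cycle.
#' @export
indirect_cost <- function(daily_wage, prop_active, employment_rate, lost_days) {
  vals <- c(daily_wage, prop_active, employment_rate, lost_days)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all inputs must be finite and >= 0", call. = FALSE)
  }
  if (prop_active > 1 || employment_rate > 1) {
    stop("`prop_active` and `employment_rate` are fractions and must be <= 1",
         call. = FALSE)
  }
  daily_wage * prop_active * employment_rate * lost_days
}

#' Calibrated indirect non-medical cost constant (KRW per 3-month cycle)
#'
#' Applied equally to both strategies when indirect costs are switched on;
#' the wage/activity/employment inputs behind it come from 2005 national
#' survey data and are not separately available.
#' @export
KRW_INDIRECT_PER_CYCLE <- 239142

#' Per-cycle cost components of the chronic LBP state
#'
#' Costs accrue only in the chronic state; acute-LBP treatment is identical
#' across strategies and the well state needs none, so both are excluded.
#'
#' @param direct_medical Direct medical cost, KRW per cycle.
#' @param direct_nonmedical Direct non-medical cost (transport, time), KRW.
#' @param indirect_nonmedical Indirect (productivity-loss) cost, KRW.
#' @param include_indirect Whether [cycle_cost_total()] adds the indirect
#'   component (base case: `FALSE`; the univariate sensitivity analysis
#'   toggles it on).
#' @return An object of class `cycle_costs`.
#' @export
cycle_costs <- function(direct_medical, direct_nonmedical,
                        indirect_nonmedical = KRW_INDIRECT_PER_CYCLE,
                        include_indirect = FALSE) {
  vals <- c(direct_medical, direct_nonmedical, indirect_nonmedical)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("cost components must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(direct_medical = direct_medical,
         direct_nonmedical = direct_nonmedical,
         indirect_nonmedical = indirect_nonmedical,
         include_indirect = isTRUE(include_indirect)),
    class = "cycle_costs"
  )
}

#' Total chronic-state cost per cycle
#'
#' @param costs A [cycle_costs()] object.
#' @return KRW per cycle: direct medical + direct non-medical, plus the
#'   indirect component when `include_indirect` is set.
#' @examples
#' uc <- cycle_costs(275740, 232036)
#' cycle_cost_total(uc)  # 507776
#' cycle_cost_total(cycle_costs(275740, 232036, include_indirect = TRUE))
#' @export
cycle_cost_total <- function(costs) {
  stopifnot(inherits(costs, "cycle_costs"))
  total <- costs$direct_medical + costs$direct_nonmedical
  if (costs$include_indirect) total <- total + costs$indirect_nonmedical
  total
}

#' Shipped base-case visit schedules
#'
#' Per-visit-type totals for the two strategies: a first visit, six regular
#' diagnosis-and-treatment visits and three simple treatment visits per
#' 3-month chronic cycle.
#'
#' @param strategy `USUAL_CARE` or `COLLABORATIVE`.
#' @return A [visit_schedule()].
#' @export
default_visit_schedule <- function(strategy = c(USUAL_CARE, COLLABORATIVE)) {
  strategy <- match.arg(strategy)
  if (strategy == USUAL_CARE) {
    visit_schedule(
      c("first visit", "regular visit (diagnosis and treatment)",
        "simple regular visit"),
      c(53983, 31685, 10549), c(1L, 6L, 3L))
  } else {
    visit_schedule(
      c("first visit", "regular visit (diagnosis and treatment)",
        "simple regular visit"),
      c(57463, 50223, 24877), c(1L, 6L, 3L))
  }
}

#' Shipped base-case cycle costs
#'
#' Direct medical costs come from [default_visit_schedule()]; direct
#' non-medical costs are 232,036 KRW (usual care) and 296,897 KRW
#' (collaborative) per cycle; the indirect component is the shared constant
#' [KRW_INDIRECT_PER_CYCLE].
#'
#' @param strategy `USUAL_CARE` or `COLLABORATIVE`.
#' @param include_indirect Include indirect non-medical costs.
#' @return A [cycle_costs()] object.
#' @export
default_cycle_costs <- function(strategy = c(USUAL_CARE, COLLABORATIVE),
                                include_indirect = FALSE) {
  strategy <- match.arg(strategy)
  dm <- visit_schedule_cost(default_visit_schedule(strategy))
  dnm <- if (strategy == USUAL_CARE) 232036 else 296897
  cycle_costs(dm, dnm, include_indirect = include_indirect)
}
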