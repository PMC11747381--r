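#' Miniature clinical-trial template schema
#'
#' A small schema with the template and slot vocabulary of the clinical-trial
#' (C-TrO-style) domain: nine templates (Arm, ClinicalTrial,
#' DiffBetweenGroups, Endpoint, Intervention, Medication, Outcome, Population,
#' Publication) whose 42 textual slots carry the standard per-slot reporting
#' names (AggregationMethod ... Title), plus `has<Template>` template-valued
#' slots wiring the nesting (ClinicalTrial at the root, arms holding
#' interventions and outcomes, outcomes holding endpoints). The topology is an
#' approximation — the full ontology is far richer — but it exercises every
#' structural feature: deep nesting, repeated fillers, textual and
#' template-valued slots. Multiplicities are left open (min 0, unbounded max).
#'
#' The same schema ships as a JSON file at
#' `system.file("extdata", "ctro_mini.json", package = "gcdecode")`.
#'
#' @return A `template_schema`.
#' @export
ctro_mini_schema <- function() {
  tx <- function(names) lapply(names, slot_def)
  tpl <- function(name, ...) lapply(list(...), function(t)
    slot_def(paste0("has", t), "template", templates = t))
  template_schema(list(
    ClinicalTrial = c(tx(c("AnalysesHealthCondition", "CTDesign", "CTduration",
                           "ConclusionComment", "ObjectiveDescription",
                           "NumberPatientsCT", "FinalNumberPatientsCT")),
                      tpl("ClinicalTrial", "Arm", "DiffBetweenGroups",
                          "Population", "Publication")),
    Arm = c(tx(c("NumberPatientsArm", "FinalNumPatientsArm", "NumberAffected",
                 "PercentageAffected")),
            tpl("Arm", "Intervention", "Outcome")),
    Intervention = c(tx(c("Frequency", "RelativeFreqTime")),
                     tpl("Intervention", "Medication")),
    Medication = tx(c("Drug", "DoseValue", "DoseUnit", "DeliveryMethod")),
    Endpoint = tx(c("EndoPointDescription", "AggregationMethod",
                    "MeasurementDevice", "BaselineUnit")),
    Outcome = c(tx(c("BaselineValue", "ChangeValue", "ObservedResult",
                     "PValueChangeValue", "RelativeChangeValue",
                     "ResultMeasuredValue", "SdDevBL", "SdDevChangeValue",
                     "SdDevResValue", "SdErrorChangeValue", "TimePoint")),
                tpl("Outcome", "Endpoint")),
    DiffBetweenGroups = tx(c("ConfIntervalDiff", "DiffGroupAbsValue",
                             "PvalueDiff")),
    Population = tx(c("Country", "Precondition")),
    Publication = tx(c("Author", "Journal", "PMID", "PublicationYear", "Title"))
  ), root = "ClinicalTrial")
}
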