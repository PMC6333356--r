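#' Sensor viewpoints
#'
#' The ten ambient sensor channels ("viewpoints") installed per household:
#' two passive infra-red presence sensors, four motion sensors on doors and
#' the pillbox, two pressure mats (bed and chair), a front-door contact and a
#' whole-home energy monitor. All carry binary activations except the energy
#' monitor, whose events carry a wattage value.
#'
#' @return `all_viewpoints()` returns the ten channel names;
#'   `sfp_viewpoints()` returns the eight channels used for activity
#'   profiling (the front door and energy monitor are excluded because both
#'   are dominated by multi-occupancy effects such as visitors, and the
#'   energy monitor aggregates over all occupants).
#' @export
all_viewpoints <- function() {
  c(
    "hallway_pir", "living_room_pir", "kitchen_motion", "pillbox_motion",
    "bedroom_door_motion", "bathroom_door_motion", "bed_pressure",
    "chair_pressure", "front_door", "energy_monitor"
  )
}

#' @rdname all_viewpoints
#' @export
sfp_viewpoints <- function() {
  setdiff(all_viewpoints(), c("front_door", "energy_monitor"))
}

#' Vital-sign parameters
#'
#' Physiological parameters captured in twice-daily measurement sessions.
#' Units: systolic/diastolic blood pressure in mmHg, pulse per minute, body
#' temperature in degrees Celsius, SpO2 in %, weight in kg, hydration in
#' arbitrary device units.
#'
#' @return Character vector of the seven parameter names.
#' @export
vital_parameters <- function() {
  c(
    "systolic_bp", "diastolic_bp", "pulse", "body_temperature",
    "spo2", "weight", "hydration"
  )
}

#' Time-of-day categories
#'
#' @return The four six-hour categories in clock order starting at midnight.
#' @export
time_categories <- function() {
  c("night", "morning", "afternoon", "evening")
}
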