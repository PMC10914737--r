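#' Class and modality registries
#'
#' Closed registries used throughout the package: the sensor modalities a
#' session may carry, the low-level activity classes produced by the
#' accelerometer network, the twelve target Activities of Daily Living (ADLs),
#' and the default room set of the monitored home.
#'
#' @name registries
NULL

# Value-column layout per modality. Appliance power and room light streams are
# registered as prefixed families (power_<appliance>, light_<room>).
.modality_cols <- list(
  accelerometer  = c("x", "y", "z"),
  step           = "value",
  light_phone    = "value",
  screen         = "event",
  app            = "app",
  location       = "room",
  fridge         = "value",
  wearable_probs = NULL # p_<class> columns, resolved at read time
)

.modality_prefixes <- c("power_", "light_")

#' Registered sensor modalities
#'
#' @return Character vector of the base modality identifiers. Appliance power
#'   (`power_<appliance>`) and room light (`light_<room>`) streams are accepted
#'   as prefixed families on top of these.
#' @export
modality_registry <- function() {
  names(.modality_cols)
}

is_registered_modality <- function(modality) {
  modality %in% names(.modality_cols) ||
    any(vapply(.modality_prefixes, function(p) startsWith(modality, p) &&
                 nchar(modality) > nchar(p), logical(1)))
}

value_cols_for <- function(modality) {
  if (modality %in% names(.modality_cols)) {
    return(.modality_cols[[modality]])
  }
  if (startsWith(modality, "power_")) return("value")
  if (startsWith(modality, "light_")) return("value")
  stop("unknown modality '", modality, "'; see modality_registry()",
       call. = FALSE)
}

#' Low-level activity classes
#'
#' The six low-level activity classes of the smartphone model, in their fixed
#' declared order (used for argmax tie-breaking). The wrist-worn input stream
#' knows five of them: it cannot see the phone, so `"on table"` is absent there.
#'
#' @param wearable If `TRUE`, return the five wearable classes (no
#'   `"on table"`).
#' @return Character vector of class names.
#' @export
lowlevel_classes <- function(wearable = FALSE) {
  if (wearable) {
    c("lying down", "running", "sitting", "standing", "walking")
  } else {
    c("lying down", "on table", "running", "sitting", "standing", "walking")
  }
}

#' The twelve target ADL classes
#'
#' Fixed order; all label matrices and model outputs use this order.
#'
#' @return Character vector of length 12.
#' @export
adl_registry <- function() {
  c("preparing drink", "preparing meal", "toileting", "eating",
    "using computer", "watching tv", "walking", "showering", "organizing",
    "using phone", "room transition", "other")
}

#' Default home configuration
#'
#' Rooms, monitored appliances and rooms with monitored lights for the home a
#' session was recorded in. The defaults mirror a single-dwelling smart home:
#' motion-triggered toilet light, a bathroom without natural light, and five
#' power-monitored appliances relevant to cooking, drink preparation and TV.
#'
#' @param rooms Character vector of room names known to the location sensor.
#' @param appliances Appliances with power-consumption monitoring.
#' @param light_rooms Rooms whose light status is monitored.
#' @return A list of class `"home_config"`.
#' @export
home_config <- function(rooms = c("kitchen", "living", "bathroom", "toilet",
                                  "bedroom", "hallway"),
                        appliances = c("cooking_plate", "cooking_hood",
                                       "kettle", "coffee_machine", "tv"),
                        light_rooms = c("toilet", "bathroom")) {
  stopifnot(length(rooms) >= 1, !anyDuplicated(rooms),
            all(light_rooms %in% rooms))
  structure(list(rooms = rooms, appliances = appliances,
                 light_rooms = light_rooms),
            class = "home_config")
}

#' Sentinel names used by the flattened confusion matrix
#' @keywords internal
.sentinels <- c(fp = "false positive", fn = "false negative")
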