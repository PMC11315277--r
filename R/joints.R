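# Joint naming conventions of the Azure Kinect Body Tracking SDK (k4abt).
# The 32 names below are in SDK index order; files that omit an explicit
# joint-name list are interpreted in this order.

.KINECT_JOINTS <- c(
  "PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK",
  "CLAVICLE_LEFT", "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
  "HAND_LEFT", "HANDTIP_LEFT", "THUMB_LEFT",
  "CLAVICLE_RIGHT", "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
  "HAND_RIGHT", "HANDTIP_RIGHT", "THUMB_RIGHT",
  "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
  "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT",
  "HEAD", "NOSE", "EYE_LEFT", "EAR_LEFT", "EYE_RIGHT", "EAR_RIGHT"
)

.INCLUDED_JOINTS <- c(
  "PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK",
  "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
  "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
  "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
  "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT"
)

#' Joint names of the body-tracking SDK
#'
#' The 32 skeletal joint names tracked by the Azure Kinect Body Tracking SDK,
#' in SDK index order. Joint-name matching throughout the package is
#' case-sensitive against this closed set.
#'
#' @return Character vector of length 32.
#' @export
#' @examples
#' kinect_joint_names()[1:4]
kinect_joint_names <- function() .KINECT_JOINTS

#' Joints used for posture and gait quality metrics
#'
#' The 18-joint subset (pelvis, spine, neck, shoulders, elbows, wrists, hips,
#' knees, ankles, feet) most relevant to gait and posture analysis. Hand
#' detail, clavicles and face landmarks are excluded.
#'
#' @return Character vector of length 18, a subset of [kinect_joint_names()].
#' @export
included_joints <- function() .INCLUDED_JOINTS

# Validate joint names against the closed SDK set (or a file's joint set).
assert_joints <- function(joints, joint_set = .KINECT_JOINTS,
                          what = "joint") {
  bad <- setdiff(joints, joint_set)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s name(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(joints)
}
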