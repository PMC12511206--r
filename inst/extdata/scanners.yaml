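# CT acquisition settings of the two audit scanners.
# The conventional-system CT appears twice because its scan range depended
# on the number of PET bed positions; the two most common ranges are kept.
# normalized_ctdiw (mGy per 100 mAs at 120 kVp, body phantom) is a
# scanner-specific constant NOT published in the audit: the values below are
# synthetic placeholders of a realistic magnitude, used only so that the
# mAs-from-CTDIvol arithmetic is runnable end to end. Replace them with the
# scanner's documented constants for real use.
scanners:
  - config_id: quadra_edge_108
    scanner_name: "Siemens Definition Edge (LAFOV system)"
    tube_voltage: 120
    slice_collimation: 0.6
    active_channels: 128
    pitch: 0.8
    scan_range: [-14, 94]
    rotation_time: 0.28
    normalized_ctdiw: 9.5   # synthetic placeholder
  - config_id: mct_as_100
    scanner_name: "Siemens Definition AS (conventional system, 100 cm range)"
    tube_voltage: 120
    slice_collimation: 1.2
    active_channels: 16
    pitch: 0.8
    scan_range: [-6, 94]
    rotation_time: 0.33
    normalized_ctdiw: 10.0  # synthetic placeholder
  - config_id: mct_as_110
    scanner_name: "Siemens Definition AS (conventional system, 110 cm range)"
    tube_voltage: 120
    slice_collimation: 1.2
    active_channels: 16
    pitch: 0.8
    scan_range: [-16, 94]
    rotation_time: 0.33
    normalized_ctdiw: 10.0  # synthetic placeholder
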