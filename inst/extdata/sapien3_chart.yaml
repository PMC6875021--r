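# Edwards Sapien 3 annulus-area sizing bands (mm^2).
# Non-overlapping transcription of the publicly available manufacturer
# sizing matrix; editable configuration data, not clinical ground truth.
device_family: Edwards Sapien 3
parameter: area_mm2
bands:
  - {lower: 273, upper: 345, size: "20"}
  - {lower: 345, upper: 430, size: "23"}
  - {lower: 430, upper: 546, size: "26"}
  - {lower: 546, upper: 683, size: "29"}
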