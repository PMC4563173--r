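shape:
- 96
- 96
- 220
spacing_mm:
- 2.0
- 2.0
- 2.0
hu_cortical:
- 1200.0
- 50.0
hu_trabecular:
- 150.0
- 50.0
hu_soft_tissue:
- 40.0
- 20.0
suv_red:
- 2.0
- 0.2
suv_yellow:
- 0.4
- 0.1
suv_background:
- 0.1
- 0.05
red_fraction:
  vertebra_thoracic: 0.95
  vertebra_lumbar: 0.95
  long_bone: 0.1
  skull: 0.05
  pelvis: 0.45
blur_fwhm_mm: 4.0
seed: 1
elements:
- shape: cylinder
  center_mm:
  - 60.0
  - 96.0
  - 51.0
  size_mm:
  - 12.0
  - 45.0
  shell_mm: 3.0
  tag: long_bone
- shape: cylinder
  center_mm:
  - 132.0
  - 96.0
  - 51.0
  size_mm:
  - 12.0
  - 45.0
  shell_mm: 3.0
  tag: long_bone
- shape: box
  center_mm:
  - 96.0
  - 96.0
  - 114.0
  size_mm:
  - 50.0
  - 20.0
  - 14.0
  shell_mm: 4.0
  tag: pelvis
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 142.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_lumbar
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 166.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_lumbar
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 190.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_lumbar
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 214.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_lumbar
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 238.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_lumbar
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 262.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_thoracic
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 286.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_thoracic
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 310.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_thoracic
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 334.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_thoracic
- shape: cylinder
  center_mm:
  - 96.0
  - 70.0
  - 358.0
  size_mm:
  - 15.0
  - 10.0
  shell_mm: 2.0
  tag: vertebra_thoracic
- shape: ellipsoid
  center_mm:
  - 96.0
  - 96.0
  - 408.0
  size_mm:
  - 30.0
  - 30.0
  - 22.0
  shell_mm: 6.0
  tag: skull
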