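# Default ROI definition for the CoMeT composites (FreeSurfer
# aparc/aseg spelling).  Cortical = 18 bilateral DKT thickness regions;
# MTL = entorhinal + parahippocampal thickness and hippocampal +
# amygdalar volume.
cortical_thickness:
  - inferiortemporal
  - temporalpole
  - superiorparietal
  - precuneus
  - supramarginal
  - superiorfrontal
  - middlefrontal
  - fusiform
  - inferiorparietal
  - superiortemporal
  - posteriorcingulate
  - isthmuscingulate
  - lateraloccipital
  - middletemporal
  - medialorbitofrontal
  - cuneus
  - lingual
  - pericalcarine
mtl_thickness:
  - entorhinal
  - parahippocampal
mtl_volume:
  - hippocampus
  - amygdala
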