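nSubjects: 30
seed: 1
spacing: 0.5
stnVolumeMean: 119.88
stnVolumeSd: 14.0
snVolumeMean: 550.0
snVolumeSd: 60.0
comSeparation:
- 6.4
- 6.7
centerJitterSd: 0.3
rotationJitterSd: 3.0
erosionProb: 0.5
stnRatio:
- 1.3
- 1.05
- 1.0
snRatio:
- 3.0
- 1.5
- 1.0
stnCenterLeft:
- -10.0
- -13.0
- -7.0
separationDir:
- 0.3
- -0.4
- -0.86
snTiltDeg: 49.0
maxFwhm: 10.0
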