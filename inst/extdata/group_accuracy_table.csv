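group,vgg19,resnet18,resnet50,resnext29_2x64d,resnext29_4x64d,fused
A1,90.55,91.60,90.78,93.12,92.51,NA
A2,85.01,87.64,87.49,87.21,88.04,NA
B1,89.29,89.44,90.23,90.14,90.92,90.32
B2,90.14,90.95,90.34,91.67,91.94,91.29
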