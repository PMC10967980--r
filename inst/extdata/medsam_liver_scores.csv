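variant,case_id,iou,dice,accuracy,precision,recall,sensitivity,f1,specificity
proposed,1,0.9635,0.9814,0.9970,0.9948,0.9683,0.9683,0.9814,0.9996
proposed,2,0.9164,0.9564,0.9902,0.9978,0.9182,0.9182,0.9564,0.9997
proposed,3,0.7682,0.8689,0.9988,0.8284,0.9135,0.9135,0.8689,0.9992
proposed,4,0.7752,0.8734,0.9923,0.8915,0.8559,0.8559,0.8734,0.9967
proposed,5,0.9009,0.9479,0.9854,0.9207,0.9766,0.9766,0.9479,0.9867
proposed,6,0.8816,0.9371,0.9846,0.9137,0.9616,0.9616,0.9371,0.9878
proposed,7,0.9367,0.9673,0.9920,0.9894,0.9462,0.9462,0.9673,0.9986
proposed,8,0.9428,0.9706,0.9908,0.9926,0.9495,0.9495,0.9706,0.9987
proposed,9,0.9577,0.9784,0.9976,0.9894,0.9676,0.9676,0.9784,0.9994
proposed,10,0.9594,0.9793,0.9933,0.9804,0.9782,0.9782,0.9793,0.9962
normalization,1,0.9576,0.9784,0.9965,0.9860,0.9709,0.9709,0.9784,0.9988
normalization,2,0.8668,0.9286,0.9828,0.9053,0.9532,0.9532,0.9286,0.9867
normalization,3,0.6667,0.8000,0.9979,0.6732,0.9856,0.9856,0.8000,0.9980
normalization,4,0.5641,0.7213,0.9767,0.5744,0.9693,0.9693,0.7213,0.9769
normalization,5,0.7928,0.8844,0.9661,0.8265,0.9511,0.9511,0.8844,0.9685
normalization,6,0.8652,0.9278,0.9816,0.8703,0.9933,0.9933,0.9278,0.9800
normalization,7,0.8661,0.9283,0.9821,0.9309,0.9256,0.9256,0.9283,0.9902
normalization,8,0.9315,0.9646,0.9885,0.9474,0.9824,0.9824,0.9646,0.9896
normalization,9,0.7801,0.8765,0.9854,0.8307,0.9276,0.9276,0.8765,0.9888
normalization,10,0.9010,0.9479,0.9826,0.9217,0.9758,0.9758,0.9479,0.9840
window,1,0.9605,0.9798,0.9968,0.9946,0.9655,0.9655,0.9798,0.9995
window,2,0.8886,0.9410,0.9869,0.9964,0.8914,0.8914,0.9410,0.9996
window,3,0.7224,0.8389,0.9986,0.8454,0.8324,0.8324,0.8389,0.9994
window,4,0.5290,0.6919,0.9725,0.5314,0.9914,0.9914,0.6919,0.9719
window,5,0.8988,0.9467,0.9855,0.9506,0.9429,0.9429,0.9467,0.9923
window,6,0.8887,0.9411,0.9857,0.9246,0.9581,0.9581,0.9411,0.9895
window,7,0.9352,0.9665,0.9918,0.9902,0.9440,0.9440,0.9665,0.9987
window,8,0.9347,0.9662,0.9891,0.9515,0.9814,0.9814,0.9662,0.9905
window,9,0.9526,0.9757,0.9973,0.9939,0.9582,0.9582,0.9757,0.9997
window,10,0.9463,0.9724,0.9910,0.9657,0.9792,0.9792,0.9724,0.9933
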