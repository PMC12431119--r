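sensor_id,sensor_type,baseline,LC,HnS,HS
TGS813,MOS,0.9699,0.705,0.4913,0.8902
TGS816,MOS,0.9968,1.2911,0.8138,0.9892
TGS826,MOS,0.906,1.5313,0.4503,2.0809
TGS832,MOS,0.6757,1.3681,1.0751,1.2122
TGS2602,MOS,0.6939,0.9404,1.0417,0.832
TGS2610,MOS,1.0321,1.4141,1.5845,1.9279
TGS2612,MOS,1.0853,0.7943,0.869,0.6879
TGS2620,MOS,0.5304,0.8607,0.848,1.2434
QCM1,QCM,0,-35.1499,-49.8205,-26.0278
QCM2,QCM,0,-22.8502,-25.2084,-26.5712
QCM3,QCM,0,-38.0843,-27.1521,-32.6932
QCM4,QCM,0,-21.3488,-19.6334,-14.7125
QCM5,QCM,0,-51.8255,-41.9895,-53.3422
QCM6,QCM,0,-16.8219,-42.1534,-28.1306
QCM7,QCM,0,-25.3295,-23.3172,-25.0235
QCM8,QCM,0,-12.6409,-21.2782,-23.1192
QCM9,QCM,0,-37.5622,-28.0442,-32.7577
QCM10,QCM,0,-20.1536,-26.9066,-11.3464
QCM11,QCM,0,-52.8489,-47.4621,-40.9131
QCM12,QCM,0,-60.5557,-24.0852,-24.57
QCM13,QCM,0,-28.5935,-28.707,-19.8002
QCM14,QCM,0,-9.9605,-21.6052,-15.1256
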