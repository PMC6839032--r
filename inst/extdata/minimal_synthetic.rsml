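<?xml version="1.0" encoding="UTF-8"?>
<rsml version="1.0">
  <metadata>
    <version>1</version>
    <unit>pixel</unit>
    <resolution>1</resolution>
    <software>hand-written synthetic fixture</software>
    <image-width>64</image-width>
    <image-height>64</image-height>
  </metadata>
  <scene>
    <plant id="1" label="plant_1" seed-x="10" seed-y="5">
      <root id="1.1" label="root_1.1">
        <geometry>
          <polyline>
            <point x="10" y="5"/>
            <point x="12" y="30"/>
            <point x="11" y="55"/>
          </polyline>
        </geometry>
      </root>
    </plant>
  </scene>
</rsml>
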